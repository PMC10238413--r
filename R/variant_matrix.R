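#' @keywords internal
"_PACKAGE"

VCLASSES <- c("SNP", "INDEL", "STR")
PROVENANCES <- c("r", "s", "f", "q", "e")

#' Build a variant annotation table
#'
#' Variants on the male-specific Y are biallelic binary characters (SNPs and
#' indels) plus, optionally, a single multi-state short tandem repeat (STR)
#' used only as a terminal haplotype splitter. Each variant carries its
#' polarization status: which allele is ancestral, established from an
#' outgroup (in horses, the donkey).
#'
#' @param id character vector of variant identifiers (e.g. `"eS0123"`). The
#'   name prefix records descriptive provenance (`r`, `s`, `f`, `q` for
#'   previously described variants, `e` for newly ascertained ones).
#' @param contig contig name(s), recycled.
#' @param pos 1-based coordinates.
#' @param ref,alt reference and alternate alleles; must differ per variant.
#' @param vclass `"SNP"`, `"INDEL"` or `"STR"`.
#' @param ancestral which allele is ancestral: `"ref"`, `"alt"` or
#'   `"unknown"` (not yet polarized).
#' @return a `data.frame` with one row per variant.
#' @export
variant_table <- function(id, contig = "Y", pos = seq_along(id),
                          ref = "A", alt = "G",
                          vclass = "SNP", ancestral = "unknown") {
  n <- length(id)
  v <- data.frame(
    id = as.character(id),
    contig = rep_len(as.character(contig), n),
    pos = rep_len(as.integer(pos), n),
    ref = rep_len(as.character(ref), n),
    alt = rep_len(as.character(alt), n),
    vclass = rep_len(as.character(vclass), n),
    ancestral = rep_len(as.character(ancestral), n),
    stringsAsFactors = FALSE
  )
  if (any(v$pos < 1)) stop("variant positions must be >= 1 (1-based)")
  if (!all(v$vclass %in% VCLASSES))
    stop("vclass must be one of ", paste(VCLASSES, collapse = ", "))
  if (!all(v$ancestral %in% c("ref", "alt", "unknown")))
    stop("ancestral must be 'ref', 'alt' or 'unknown'")
  bad <- v$vclass != "STR" & v$ref == v$alt
  if (any(bad)) stop("ref and alt alleles identical for: ",
                     paste(v$id[bad], collapse = ", "))
  badsnp <- v$vclass == "SNP" & (nchar(v$ref) != 1L | nchar(v$alt) != 1L)
  if (any(badsnp)) stop("SNP alleles must be single bases: ",
                        paste(v$id[badsnp], collapse = ", "))
  v$provenance <- ifelse(substr(v$id, 1, 1) %in% PROVENANCES,
                         substr(v$id, 1, 1), NA_character_)
  v
}

#' Construct a polarized sample-by-variant matrix
#'
#' The central object of the pipeline: haploid genotypes over biallelic
#' variants recoded against an outgroup into 0 = ancestral, 1 = derived,
#' `NA` = missing. Rows are samples, columns variants.
#'
#' @param states integer matrix over \{0, 1, NA\}; rows samples, columns
#'   variants. Dimnames are used for sample and variant ids when `samples` /
#'   `variants` are not given.
#' @param variants optional variant table (see [variant_table()]); defaults
#'   to an autogenerated SNP table with `ancestral = "ref"`.
#' @param samples optional character vector of sample ids.
#' @param groups optional named character vector mapping sample id to a
#'   group label (region/breed).
#' @param str_alleles optional named integer vector of per-sample repeat
#'   counts for the single STR, used only as a terminal haplotype splitter.
#' @return an object of class `polarized_matrix`.
#' @export
polarized_matrix <- function(states, variants = NULL, samples = NULL,
                             groups = NULL, str_alleles = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (is.null(samples)) samples <- rownames(states)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(states)))
  if (is.null(variants)) {
    ids <- colnames(states)
    if (is.null(ids)) ids <- sprintf("eS%04d", seq_len(ncol(states)))
    variants <- variant_table(ids, ancestral = "ref")
  }
  if (length(samples) != nrow(states))
    stop("length(samples) != nrow(states)")
  if (nrow(variants) != ncol(states))
    stop("nrow(variants) != ncol(states)")
  ok <- states %in% c(0L, 1L) | is.na(states)
  if (!all(ok)) stop("states must be 0, 1 or NA")
  dimnames(states) <- list(samples, variants$id)
  if (!is.null(groups)) {
    groups <- groups[samples]
    names(groups) <- samples
  }
  structure(
    list(samples = samples, variants = variants, states = states,
         groups = groups, str_alleles = str_alleles),
    class = "polarized_matrix"
  )
}

#' @export
print.polarized_matrix <- function(x, ...) {
  cat(sprintf("polarized_matrix: %d samples x %d variants (%.1f%% missing)\n",
              length(x$samples), nrow(x$variants),
              100 * mean(is.na(x$states))))
  pol <- sum(x$variants$ancestral != "unknown")
  cat(sprintf("  polarized variants: %d; classes: %s\n", pol,
              paste(names(table(x$variants$vclass)),
                    table(x$variants$vclass), sep = "=", collapse = " ")))
  invisible(x)
}

#' @export
dim.polarized_matrix <- function(x) dim(x$states)

#' Subset a polarized matrix by samples and/or variants
#'
#' @param x a `polarized_matrix`.
#' @param samples,variants character vectors of ids (or logical/integer
#'   indices) to retain, in the given order.
#' @return a `polarized_matrix`.
#' @export
subset_matrix <- function(x, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_along(x$samples) else {
    if (is.character(samples)) match(samples, x$samples) else which(
      if (is.logical(samples)) samples else seq_along(x$samples) %in% samples)
  }
  if (anyNA(si)) stop("unknown samples: ",
                      paste(samples[is.na(si)], collapse = ", "))
  vi <- if (is.null(variants)) seq_len(nrow(x$variants)) else {
    if (is.character(variants)) match(variants, x$variants$id) else which(
      if (is.logical(variants)) variants else
        seq_len(nrow(x$variants)) %in% variants)
  }
  if (anyNA(vi)) stop("unknown variants")
  polarized_matrix(x$states[si, vi, drop = FALSE],
                   variants = x$variants[vi, , drop = FALSE],
                   samples = x$samples[si],
                   groups = x$groups,
                   str_alleles = x$str_alleles)
}

# ---- VCF ingestion -----------------------------------------------------

#' Read haploid genotypes from a VCF
#'
#' Reads Y-chromosome calls into a raw allele matrix. The Y is haploid, so
#' diploid-encoded heterozygous genotypes are treated as missing (they
#' signal mapping artefacts rather than real heterozygosity) with a warning.
#' Multiallelic records are split into one biallelic record per alternate
#' allele.
#'
#' @param path path to a VCF 4.x file (uncompressed or bgzipped).
#' @param sample_subset optional character vector restricting (and ordering)
#'   the samples read.
#' @return a list of class `allele_matrix` with elements `samples`,
#'   `variants` (a [variant_table()] without polarization) and `calls`, a
#'   character matrix of called alleles (`NA` = missing).
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf requires the VariantAnnotation package")
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  samples <- colnames(gt)
  if (!is.null(sample_subset)) {
    miss <- setdiff(sample_subset, samples)
    if (length(miss)) stop("samples absent from VCF: ",
                           paste(miss, collapse = ", "))
    gt <- gt[, sample_subset, drop = FALSE]
    samples <- sample_subset
  }
  if (length(samples) == 0L) stop("VCF contains zero samples")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- lapply(rr$ALT, as.character)
  contig <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ids <- names(rr)
  if (is.null(ids)) ids <- paste0(contig, "_", pos)

  # split multiallelics; convert GT strings to allele characters
  out_id <- character(0); out_contig <- character(0); out_pos <- integer(0)
  out_ref <- character(0); out_alt <- character(0)
  calls <- NULL
  n_het <- 0L
  for (i in seq_along(ids)) {
    alts <- altl[[i]]
    alts <- alts[nzchar(alts)]
    if (length(alts) == 0L) next
    g <- gt[i, ]
    # allele index per sample; "." missing, het -> NA
    first <- sub("[/|].*$", "", g)
    second <- ifelse(grepl("[/|]", g), sub("^.*[/|]", "", g), first)
    het <- !is.na(first) & first != "." & second != "." & first != second
    n_het <- n_het + sum(het)
    idx <- suppressWarnings(as.integer(first))
    idx[het | is.na(first) | first == "."] <- NA_integer_
    alleles <- c(ref[i], alts)
    called <- alleles[idx + 1L]
    for (k in seq_along(alts)) {
      vid <- if (length(alts) == 1L) ids[i] else paste0(ids[i], ".", k)
      out_id <- c(out_id, vid)
      out_contig <- c(out_contig, contig[i])
      out_pos <- c(out_pos, pos[i])
      out_ref <- c(out_ref, ref[i])
      out_alt <- c(out_alt, alts[k])
      # calls of a non-focal alt allele are missing for this split record
      ck <- called
      ck[!is.na(ck) & !(ck %in% c(ref[i], alts[k]))] <- NA_character_
      calls <- rbind(calls, ck)
    }
  }
  if (n_het > 0L)
    warning(n_het, " diploid-heterozygous call(s) set to missing ",
            "(haploid chromosome contract)")
  if (is.null(calls)) stop("VCF contains no usable biallelic records")
  vclass <- ifelse(nchar(out_ref) == 1L & nchar(out_alt) == 1L,
                   "SNP", "INDEL")
  variants <- variant_table(out_id, contig = out_contig, pos = out_pos,
                            ref = out_ref, alt = out_alt, vclass = vclass)
  calls <- t(calls)  # samples x variants
  dimnames(calls) <- list(samples, out_id)
  structure(list(samples = samples, variants = variants, calls = calls),
            class = "allele_matrix")
}

#' Polarize an allele matrix against an outgroup
#'
#' The outgroup's allele at each variant is taken as the ancestral state;
#' samples carrying the other allele are derived (state 1). Variants at which
#' the outgroup is missing cannot be polarized: they get
#' `ancestral = "unknown"` and all-missing states, and are flagged in the
#' `unpolarized` attribute. The outgroup is removed from the sample set.
#'
#' @param x an `allele_matrix` (from [read_vcf()]) or a `polarized_matrix`
#'   whose states are coded against the reference (`0` = ref, `1` = alt), in
#'   which case the outgroup's row re-orients the coding. Polarizing twice
#'   with the same outgroup is a no-op.
#' @param outgroup_sample sample id of the outgroup (e.g. the donkey).
#' @return a `polarized_matrix`; attribute `unpolarized` lists variant ids
#'   with unknown ancestral state.
#' @export
polarize <- function(x, outgroup_sample) {
  UseMethod("polarize")
}

#' @export
polarize.allele_matrix <- function(x, outgroup_sample) {
  oi <- match(outgroup_sample, x$samples)
  if (is.na(oi)) stop("outgroup sample not found: ", outgroup_sample)
  og <- x$calls[oi, ]
  keep <- setdiff(seq_along(x$samples), oi)
  v <- x$variants
  v$ancestral <- ifelse(is.na(og), "unknown",
                        ifelse(og == v$ref, "ref",
                               ifelse(og == v$alt, "alt", "unknown")))
  states <- matrix(NA_integer_, length(keep), nrow(v))
  for (j in seq_len(nrow(v))) {
    if (v$ancestral[j] == "unknown") next
    anc <- if (v$ancestral[j] == "ref") v$ref[j] else v$alt[j]
    der <- if (v$ancestral[j] == "ref") v$alt[j] else v$ref[j]
    cj <- x$calls[keep, j]
    states[, j] <- ifelse(is.na(cj), NA_integer_,
                          ifelse(cj == der, 1L,
                                 ifelse(cj == anc, 0L, NA_integer_)))
  }
  pm <- polarized_matrix(states, variants = v, samples = x$samples[keep])
  attr(pm, "unpolarized") <- v$id[v$ancestral == "unknown"]
  pm
}

#' @export
polarize.polarized_matrix <- function(x, outgroup_sample) {
  oi <- match(outgroup_sample, x$samples)
  if (is.na(oi)) stop("outgroup sample not found: ", outgroup_sample)
  og <- x$states[oi, ]
  keep <- setdiff(seq_along(x$samples), oi)
  v <- x$variants
  states <- x$states[keep, , drop = FALSE]
  flip <- !is.na(og) & og == 1L
  states[, flip] <- 1L - states[, flip, drop = FALSE]
  # outgroup state 0 keeps orientation; missing outgroup -> unknown
  prev <- v$ancestral
  v$ancestral <- ifelse(is.na(og), "unknown",
                        ifelse(og == 0L, ifelse(prev == "alt", "alt", "ref"),
                               ifelse(prev == "ref", "alt", "ref")))
  states[, v$ancestral == "unknown"] <- NA_integer_
  pm <- polarized_matrix(states, variants = v, samples = x$samples[keep],
                         groups = x$groups, str_alleles = x$str_alleles)
  attr(pm, "unpolarized") <- v$id[v$ancestral == "unknown"]
  pm
}

# ---- Filtering ---------------------------------------------------------

#' Filtering configuration
#'
#' Thresholds for the stringent variant/sample filter. The exact thresholds
#' behind published stringently filtered call sets are study-specific; these
#' defaults are permissive enough to keep target-enriched samples while
#' stabilizing tree building, and every applied value is echoed in the
#' filter report.
#'
#' @param max_site_missing maximum tolerated fraction of missing calls per
#'   variant (default 0.2).
#' @param max_sample_missing maximum tolerated fraction of missing calls per
#'   sample (default 0.3).
#' @param require_polarized drop variants with unknown ancestral state.
#' @param require_biallelic drop variants flagged non-biallelic.
#' @param mark_singletons flag (not remove) variants whose derived allele is
#'   observed in exactly one sample.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(max_site_missing = 0.2, max_sample_missing = 0.3,
                          require_polarized = TRUE, require_biallelic = TRUE,
                          mark_singletons = TRUE) {
  for (t in c(max_site_missing, max_sample_missing))
    if (!is.numeric(t) || t < 0 || t > 1)
      stop("missingness thresholds must lie in [0, 1]")
  structure(list(max_site_missing = max_site_missing,
                 max_sample_missing = max_sample_missing,
                 require_polarized = require_polarized,
                 require_biallelic = require_biallelic,
                 mark_singletons = mark_singletons),
            class = "filter_config")
}

#' Stringent variant and sample filtering
#'
#' Applies, in order: (i) biallelic; (ii) polarized (known ancestral state);
#' (iii) per-site missingness; (iv) per-sample missingness. Singleton
#' variants are retained but marked (they can be validated individually,
#' e.g. by KASP genotyping). The report reconciles exactly:
#' removed + retained = input, per axis.
#'
#' @param x a `polarized_matrix`.
#' @param config a [filter_config()].
#' @return list with `matrix` (filtered `polarized_matrix`, with a logical
#'   `singleton` column added to its variant table) and `report` (class
#'   `filter_report`).
#' @export
filter_stringent <- function(x, config = filter_config()) {
  stopifnot(inherits(x, "polarized_matrix"))
  if (!inherits(config, "filter_config")) stop("config must be a filter_config")
  v <- x$variants
  nv0 <- nrow(v); ns0 <- length(x$samples)
  keep <- rep(TRUE, nv0)
  removed <- c(non_biallelic = 0L, unpolarized = 0L, site_missing = 0L)

  if (config$require_biallelic) {
    bial <- if ("biallelic" %in% names(v)) v$biallelic else rep(TRUE, nv0)
    bial <- bial & v$vclass != "STR"  # the STR is multi-state by definition
    removed["non_biallelic"] <- sum(keep & !bial)
    keep <- keep & bial
  }
  if (config$require_polarized) {
    pol <- v$ancestral != "unknown"
    removed["unpolarized"] <- sum(keep & !pol)
    keep <- keep & pol
  }
  sm <- colMeans(is.na(x$states))
  okm <- sm <= config$max_site_missing
  removed["site_missing"] <- sum(keep & !okm)
  keep <- keep & okm

  st <- x$states[, keep, drop = FALSE]
  sampm <- rowMeans(is.na(st))
  keeps <- sampm <= config$max_sample_missing
  removed_samples <- c(sample_missing = sum(!keeps))

  st <- st[keeps, , drop = FALSE]
  vkeep <- v[keep, , drop = FALSE]
  dac <- colSums(st == 1L, na.rm = TRUE)
  vkeep$singleton <- if (config$mark_singletons) dac == 1L else FALSE

  out <- polarized_matrix(st, variants = vkeep,
                          samples = x$samples[keeps],
                          groups = x$groups, str_alleles = x$str_alleles)
  report <- structure(list(
    removed_variants = removed,
    removed_samples = removed_samples,
    retained_variants = sum(keep),
    retained_samples = sum(keeps),
    input_variants = nv0,
    input_samples = ns0,
    n_singletons = sum(vkeep$singleton),
    config = config
  ), class = "filter_report")
  stopifnot(sum(removed) + report$retained_variants == nv0,
            sum(removed_samples) + report$retained_samples == ns0)
  list(matrix = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report\n")
  cat(sprintf("  variants: %d in, %d retained (removed: %s)\n",
              x$input_variants, x$retained_variants,
              paste(names(x$removed_variants), x$removed_variants,
                    sep = "=", collapse = " ")))
  cat(sprintf("  samples:  %d in, %d retained (removed: %s)\n",
              x$input_samples, x$retained_samples,
              paste(names(x$removed_samples), x$removed_samples,
                    sep = "=", collapse = " ")))
  cat(sprintf("  singleton variants marked: %d\n", x$n_singletons))
  invisible(x)
}

# ---- Haplotype strings -------------------------------------------------

#' Concatenate allelic states into haplotype strings
#'
#' A haplotype (HT) is the ordered concatenation of a sample's allelic
#' states across all variants; the STR repeat count, when present, is
#' appended as a final multi-state symbol so that samples identical at all
#' binary variants but differing in repeat number form distinct HTs.
#'
#' @param x a `polarized_matrix`.
#' @param impute_policy `"raw"` keeps samples with missing calls (missing
#'   coded `.` in the string); `"require_complete"` excludes any sample with
#'   a missing call from the distinct-HT count.
#' @return list with `haplotypes` (named character vector over included
#'   samples) and `n_distinct`.
#' @export
haplotype_strings <- function(x, impute_policy = c("raw", "require_complete")) {
  impute_policy <- match.arg(impute_policy)
  st <- x$states
  chr <- matrix(as.character(st), nrow(st), ncol(st))
  chr[is.na(chr)] <- "."
  hap <- apply(chr, 1, paste0, collapse = "")
  names(hap) <- x$samples
  if (!is.null(x$str_alleles)) {
    stra <- x$str_alleles[x$samples]
    hap <- paste0(hap, "|", ifelse(is.na(stra), ".", stra))
    names(hap) <- x$samples
  }
  if (impute_policy == "require_complete") {
    complete <- !apply(is.na(st), 1, any)
    if (!is.null(x$str_alleles))
      complete <- complete & !is.na(x$str_alleles[x$samples])
    hap <- hap[complete]
  }
  list(haplotypes = hap, n_distinct = length(unique(hap)))
}

# ---- Tabular serialization --------------------------------------------

#' Write / read the tab-separated matrix interchange format
#'
#' Header row = variant ids, first column = sample id, cells in
#' \{0, 1, NA\}. A companion `<path>.variants.tsv` carries the variant
#' annotation so polarization survives the round trip.
#'
#' @param x a `polarized_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(sample = x$samples, x$states, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$variants, paste0(path, ".variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  st <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(st) <- "integer"
  rownames(st) <- df$sample
  vpath <- paste0(path, ".variants.tsv")
  v <- NULL
  if (file.exists(vpath)) {
    v <- utils::read.table(vpath, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    v <- v[match(colnames(st), v$id), , drop = FALSE]
    rownames(v) <- NULL
  }
  polarized_matrix(st, variants = v, samples = df$sample)
}
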