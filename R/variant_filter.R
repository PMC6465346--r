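# Staged haploid-aware variant filtering and phylogenetic imputation.
#
# The Y is haploid, so heterozygous calls are treated as unreliable
# evidence: they count with no-calls toward the missingness threshold and
# as missing when haplotypes are built.

#' Construct a variant call set
#'
#' Container for a VCF-like call set: per-variant metadata plus
#' variants-by-samples matrices of categorical genotype, depth, genotype
#' quality and phasing flags.
#'
#' @param meta data.frame with columns `id`, `contig`, `pos` (1-based),
#'   `ref`, `alt` (comma-separated for multi-allelic records),
#'   `marker_type` (`SNV`, `indel` or `STR`) and optionally
#'   `reference_error` (logical).
#' @param gt character matrix (variants x samples) with entries in
#'   `ref`, `alt`, `het`, `missing`.
#' @param dp,gq non-negative integer matrices of read depth and genotype
#'   quality, same shape as `gt`.
#' @param phased logical matrix, `TRUE` where the sample's genotype used
#'   the phased separator.
#' @return an object of class `variant_set`.
#' @export
variant_set <- function(meta, gt, dp, gq, phased) {
  stopifnot(is.data.frame(meta),
            all(c("id", "contig", "pos", "ref", "alt", "marker_type")
                %in% names(meta)),
            nrow(meta) == nrow(gt),
            all(dim(gt) == dim(dp)), all(dim(gt) == dim(gq)),
            all(dim(gt) == dim(phased)),
            !is.null(colnames(gt)))
  bad <- !gt %in% c("ref", "alt", "het", "missing")
  if (any(bad)) stop("invalid genotype code(s): ",
                     paste(unique(gt[bad]), collapse = ", "))
  if (is.null(meta$reference_error)) meta$reference_error <- FALSE
  if (anyDuplicated(meta$id)) stop("duplicated variant ids")
  rownames(gt) <- rownames(dp) <- rownames(gq) <- rownames(phased) <- meta$id
  structure(list(meta = meta, gt = gt, dp = dp, gq = gq, phased = phased),
            class = "variant_set")
}

#' @export
`[.variant_set` <- function(x, i) {
  variant_set(x$meta[i, , drop = FALSE], x$gt[i, , drop = FALSE],
              x$dp[i, , drop = FALSE], x$gq[i, , drop = FALSE],
              x$phased[i, , drop = FALSE])
}

#' @export
length.variant_set <- function(x) nrow(x$meta)

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$meta), "variants x", ncol(x$gt), "samples\n")
  print(table(x$meta$marker_type))
  invisible(x)
}

#' Variant filter parameters
#'
#' @param min_depth minimum read depth; a variant is kept when at least
#'   one sample reaches both `min_depth` and `min_gq` (boundaries
#'   inclusive).
#' @param min_gq minimum genotype quality, paired with `min_depth`.
#' @param max_badcall_frac variants whose fraction of heterozygous or
#'   missing calls exceeds this (strictly) are removed.
#' @return list of class `filter_params`.
#' @export
filter_params <- function(min_depth = 3L, min_gq = 9L,
                          max_badcall_frac = 0.10) {
  stopifnot(min_depth >= 0, min_gq >= 0,
            max_badcall_frac >= 0, max_badcall_frac <= 1)
  structure(list(min_depth = as.integer(min_depth),
                 min_gq = as.integer(min_gq),
                 max_badcall_frac = max_badcall_frac),
            class = "filter_params")
}

.variants_sorted <- function(meta) {
  ord <- order(meta$contig, meta$pos)
  identical(ord, seq_len(nrow(meta)))
}

#' Sort a variant set by (contig, pos)
#' @param x a [variant_set()].
#' @return the sorted `variant_set`.
#' @export
sort_variants <- function(x) x[order(x$meta$contig, x$meta$pos)]

#' Flag reference errors
#'
#' A site is flagged as a reference error when every non-missing call —
#' including the outgroup — carries the alternate allele: no sampled
#' lineage supports the reference base, so the assembly itself is the
#' most parsimonious source of the mismatch. (This operational criterion
#' is a completion; flagged records carry it in `meta$reference_error`.)
#'
#' @param x a [variant_set()].
#' @param outgroup_id sample id of the outgroup.
#' @return `x` with `meta$reference_error` updated.
#' @export
detect_reference_errors <- function(x, outgroup_id) {
  if (!outgroup_id %in% colnames(x$gt))
    stop("outgroup sample not in call set: ", outgroup_id)
  informative <- x$gt %in% c("ref", "alt")
  dim(informative) <- dim(x$gt)
  alt_fixed <- rowSums(x$gt == "alt") > 0 &
    rowSums(x$gt == "ref") == 0 & rowSums(informative) > 0
  x$meta$reference_error <- alt_fixed & x$gt[, outgroup_id] == "alt"
  x
}

#' Staged variant-quality filter over scY regions
#'
#' Applies, in order: (1) restriction to variants inside single-copy Y
#' (scY) windows; (2) removal of phased records (gene-conversion
#' suspects), multi-allelic records and flagged reference errors;
#' (3) removal of variants lacking any call with depth >= `min_depth`
#' and genotype quality >= `min_gq`; (4) removal of variants with
#' heterozygous or missing calls in more than `max_badcall_frac` of the
#' samples (strict inequality).
#'
#' @param x a [variant_set()], sorted by (contig, pos).
#' @param scy_regions a `GRanges` of scY windows (non-overlapping,
#'   sorted), e.g. from [read_bed()].
#' @param params a [filter_params()].
#' @param outgroup_id if supplied, [detect_reference_errors()] is run
#'   first with this outgroup.
#' @return list with `kept` (a `variant_set`) and `report` (data.frame
#'   of per-stage removal counts; stages sum to input minus output).
#' @export
filter_variants <- function(x, scy_regions, params = filter_params(),
                            outgroup_id = NULL) {
  stopifnot(inherits(x, "variant_set"))
  if (!.variants_sorted(x$meta))
    stop("variants must be sorted by (contig, pos); see sort_variants()")
  if (length(scy_regions) == 0) stop("scY region set is empty")
  if (!is.null(outgroup_id)) x <- detect_reference_errors(x, outgroup_id)

  n_samples <- ncol(x$gt)
  stages <- c("not_scY", "phased", "multiallelic", "reference_error",
              "low_quality", "high_missingness")
  removed <- setNames(integer(length(stages)), stages)

  gr <- GenomicRanges::GRanges(
    x$meta$contig, IRanges::IRanges(start = x$meta$pos, width = 1L))
  # seqlevel mismatches are expected (variants on contigs with no scY
  # window simply fail the overlap)
  in_scy <- suppressWarnings(IRanges::overlapsAny(gr, scy_regions))
  removed["not_scY"] <- sum(!in_scy)
  x <- x[in_scy]

  is_phased <- rowSums(x$phased) > 0
  removed["phased"] <- sum(is_phased)
  x <- x[!is_phased]

  n_alt <- lengths(strsplit(as.character(x$meta$alt), ",", fixed = TRUE))
  multi <- n_alt > 1
  removed["multiallelic"] <- sum(multi)
  x <- x[!multi]

  removed["reference_error"] <- sum(x$meta$reference_error)
  x <- x[!x$meta$reference_error]

  good_call <- rowSums(x$dp >= params$min_depth & x$gq >= params$min_gq) > 0
  removed["low_quality"] <- sum(!good_call)
  x <- x[good_call]

  bad_frac <- rowMeans(x$gt == "het" | x$gt == "missing")
  high_miss <- bad_frac > params$max_badcall_frac
  removed["high_missingness"] <- sum(high_miss)
  x <- x[!high_miss]

  list(kept = x,
       report = data.frame(stage = stages, removed = as.integer(removed),
                           stringsAsFactors = FALSE))
}

#' Impute missing haplotype states by phylogenetic clustering
#'
#' Residual missing (or heterozygous, already coded missing) entries in a
#' polarized haplotype matrix are replaced by the majority state among
#' the sample's `k` nearest neighbours, where distance is the Hamming
#' count of mismatches over mutually non-missing sites. Ties — in the
#' neighbour vote or when no neighbour is informative — resolve to the
#' ancestral state (0). Non-missing entries are never altered.
#'
#' @param mat a [haplo_matrix()] (states 0 = ancestral, 1 = derived,
#'   `NA` = missing).
#' @param k number of nearest neighbours (>= 1).
#' @return list with `matrix` (completed `haplo_matrix`) and `changes`
#'   (data.frame `sample`, `site`, `state` listing every edit).
#' @export
impute_by_clustering <- function(mat, k = 3L) {
  stopifnot(inherits(mat, "haplo_matrix"), k >= 1)
  S <- unclass_states(mat)
  all_missing <- rowSums(!is.na(S)) == 0
  if (any(all_missing))
    stop("sample(s) with all-missing rows: ",
         paste(rownames(S)[all_missing], collapse = ", "))
  changes <- list()
  for (i in which(rowSums(is.na(S)) > 0)) {
    d <- vapply(seq_len(nrow(S)), function(j) {
      ok <- !is.na(S[i, ]) & !is.na(S[j, ])
      if (!any(ok)) return(NA_real_)
      sum(S[i, ok] != S[j, ok])
    }, numeric(1))
    d[i] <- NA
    nbr <- order(d, na.last = NA)[seq_len(min(k, sum(!is.na(d))))]
    for (s in which(is.na(S[i, ]))) {
      votes <- S[nbr, s]
      votes <- votes[!is.na(votes)]
      state <- if (length(votes) == 0) 0L
               else if (sum(votes == 1) > sum(votes == 0)) 1L
               else if (sum(votes == 1) < sum(votes == 0)) 0L
               else 0L  # tie -> ancestral
      S[i, s] <- state
      changes[[length(changes) + 1L]] <-
        data.frame(sample = rownames(S)[i], site = colnames(S)[s],
                   state = state, stringsAsFactors = FALSE)
    }
  }
  changes <- if (length(changes)) do.call(rbind, changes)
    else data.frame(sample = character(), site = character(),
                    state = integer(), stringsAsFactors = FALSE)
  list(matrix = haplo_matrix(S, outgroup_id = attr(mat, "outgroup_id"),
                             polarized = attr(mat, "polarized") %||% FALSE),
       changes = changes)
}
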