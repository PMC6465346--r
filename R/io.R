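# Readers and writers for the pipeline's plain-text dialects.
# BED intervals are 0-based half-open; VCF positions are 1-based; the
# conversion happens exactly once, at this boundary.

#' Read a per-window coverage table
#'
#' TSV with columns `contig`, `start`, `end` (0-based half-open) and one
#' raw-coverage column per sample. Rows must be sorted by (contig,
#' start) and unique.
#'
#' @param path file path.
#' @return list with `windows` (data.frame) and `samples` (character).
#' @export
read_coverage_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("contig", "start", "end")
  if (!all(need %in% names(df)))
    stop("coverage table must have columns contig, start, end")
  samples <- setdiff(names(df), need)
  key <- paste(df$contig, df$start)
  if (anyDuplicated(key))
    stop("duplicate window at line ",
         which(duplicated(key))[1] + 1L, " of ", path)
  ord <- order(df$contig, df$start)
  if (!identical(ord, seq_len(nrow(df)))) {
    bad <- which(ord != seq_len(nrow(df)))[1]
    stop("coverage table not sorted by (contig, start); first offending line ",
         bad + 1L, " of ", path)
  }
  for (s in samples) if (any(!is.finite(df[[s]])) || any(df[[s]] < 0))
    stop("malformed coverage for sample ", s)
  list(windows = df, samples = samples)
}

#' Write a per-window coverage table
#' @param windows data.frame as produced by [simulate_coverage()].
#' @param path output path.
#' @export
write_coverage_table <- function(windows, path) {
  write.table(windows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample profile tables
#'
#' TSV with columns `sample_id`, `sex`, `c`, `b` (b empty/NA for males).
#'
#' @param path file path.
#' @return a validated profile data.frame (see [sample_profiles()]).
#' @export
read_profiles <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  sample_profiles(df$sample_id, df$sex, df$c, df$b)
}

#' @rdname read_profiles
#' @param profiles a profile data.frame.
#' @export
write_profiles <- function(profiles, path) {
  write.table(profiles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED file of regions
#' @param path BED3+ file (0-based half-open).
#' @return a `GRanges`.
#' @export
read_bed <- function(path) rtracklayer::import(path, format = "BED")

#' Write classified windows as BED
#'
#' Name field carries the class label; score is `round(1000 *
#' posterior_msy)` (BED scores are capped at 1000).
#'
#' @param classes output of [classify_windows()].
#' @param path output path.
#' @export
write_classes_bed <- function(classes, path) {
  gr <- GenomicRanges::GRanges(
    classes$contig,
    IRanges::IRanges(start = classes$start + 1L, end = classes$end))
  S4Vectors::mcols(gr)$name <- as.character(classes$label)
  S4Vectors::mcols(gr)$score <- round(1000 * classes$posterior_msy)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

.gt_code <- function(gt) {
  # map one VCF GT string (haploid or diploid, phased or not) to a
  # categorical call
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".") || length(alleles) == 0) return("missing")
  u <- unique(alleles)
  if (length(u) > 1) return("het")
  if (u == "0") "ref" else "alt"
}

#' Read a VCF into a variant set
#'
#' Accepts uncompressed VCF 4.x with per-sample GT, DP and GQ. Both
#' haploid (`0`, `1`) and diploid-coded (`0/0`, `0/1`, `1/1`) genotypes
#' are accepted; `0/1` maps to a heterozygous call and any genotype
#' written with the phased separator `|` sets the record's phased flag
#' for that sample. Raw body lines are retained so filtered output can
#' round-trip byte-identically.
#'
#' @param path VCF file path.
#' @return a [variant_set()] with attributes `header_lines` and
#'   `body_lines` for pass-through writing.
#' @export
read_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "assembly")
  g <- VariantAnnotation::geno(vcf)
  for (f in c("GT", "DP", "GQ"))
    if (!f %in% names(g))
      stop("VCF FORMAT lacks required field: ", f)
  gt_raw <- g$GT
  gt <- apply(gt_raw, c(1, 2), .gt_code)
  phased <- apply(gt_raw, c(1, 2), function(x) grepl("|", x, fixed = TRUE))
  dp <- g$DP; dp[is.na(dp)] <- 0L
  gq <- g$GQ; gq[is.na(gq)] <- 0L
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- vapply(VariantAnnotation::alt(vcf), function(a)
    paste(as.character(a), collapse = ","), character(1))
  alt_list <- strsplit(alt, ",", fixed = TRUE)
  marker <- ifelse(nchar(ref) == 1 &
                     vapply(alt_list, function(a) all(nchar(a) == 1),
                            logical(1)),
                   "SNV", "indel")
  info <- VariantAnnotation::info(vcf)
  if ("STR" %in% names(info)) marker[info$STR %in% TRUE] <- "STR"
  ids <- names(rr)
  if (is.null(ids) || anyDuplicated(ids) || any(ids == "."))
    ids <- paste0(as.character(GenomicRanges::seqnames(rr)), ":",
                  GenomicRanges::start(rr))
  meta <- data.frame(id = ids,
                     contig = as.character(GenomicRanges::seqnames(rr)),
                     pos = GenomicRanges::start(rr),
                     ref = ref, alt = alt, marker_type = marker,
                     stringsAsFactors = FALSE)
  vs <- variant_set(meta, gt, matrix(as.integer(dp), nrow(gt),
                                     dimnames = dimnames(gt)),
                    matrix(as.integer(gq), nrow(gt),
                           dimnames = dimnames(gt)), phased)
  lines <- readLines(path)
  attr(vs, "header_lines") <- lines[startsWith(lines, "#")]
  attr(vs, "body_lines") <- lines[!startsWith(lines, "#")]
  vs
}

#' Write kept variants as VCF with FILTER annotation
#'
#' Body lines of the input VCF pass through unchanged except for the
#' FILTER column: kept records read `PASS`, removed records carry their
#' removal stage. By default only kept records are written.
#'
#' @param x the `variant_set` returned by [read_vcf()] (it carries the
#'   raw lines).
#' @param kept_ids variant ids retained by [filter_variants()].
#' @param path output path.
#' @param stage_of optional named character vector id -> removal stage.
#' @param keep_only write only kept records (default `TRUE`).
#' @export
write_vcf_filtered <- function(x, kept_ids, path, stage_of = NULL,
                               keep_only = TRUE) {
  header <- attr(x, "header_lines")
  body <- attr(x, "body_lines")
  if (is.null(header) || is.null(body))
    stop("variant set does not carry raw VCF lines (not from read_vcf())")
  fields <- strsplit(body, "\t", fixed = TRUE)
  keep <- x$meta$id %in% kept_ids
  out <- vapply(seq_along(body), function(i) {
    f <- fields[[i]]
    f[7] <- if (keep[i]) "PASS"
            else unname(stage_of[x$meta$id[i]] %||% "filtered")
    paste(f, collapse = "\t")
  }, character(1))
  if (keep_only) out <- out[keep]
  writeLines(c(header, out), path)
  invisible(path)
}

#' Read / write a haplotype matrix as TSV
#'
#' Rows are samples, columns variant ids, cells `0`, `1` or `.`.
#'
#' @param path file path.
#' @param outgroup_id outgroup sample name.
#' @param polarized whether states are already ancestral/derived coded.
#' @return a [haplo_matrix()].
#' @export
read_haplo_matrix <- function(path, outgroup_id, polarized = FALSE) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                   check.names = FALSE, colClasses = "character")
  S <- as.matrix(df)
  S[S == "."] <- NA
  mode(S) <- "integer"
  haplo_matrix(S, outgroup_id, polarized = polarized)
}

#' @rdname read_haplo_matrix
#' @param mat a [haplo_matrix()].
#' @export
write_haplo_matrix <- function(mat, path) {
  S <- unclass_states(mat)
  out <- matrix(as.character(S), nrow(S), dimnames = dimnames(S))
  out[is.na(out)] <- "."
  write.table(data.frame(sample = rownames(out), out, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a clade tree as Newick plus a branch-variant sidecar
#'
#' The Newick branch lengths are per-branch mutation counts; the sidecar
#' TSV maps each branch (keyed by child node) to the variant ids that
#' mutated on it.
#'
#' @param tree a `clade_tree`.
#' @param path Newick output path; the sidecar is `path` +
#'   `.branches.tsv`.
#' @export
write_clade_tree <- function(tree, path) {
  ape::write.tree(as_phylo(tree), path)
  side <- data.frame(
    branch = names(tree$branch_sites),
    mutations = lengths(tree$branch_sites),
    variants = vapply(tree$branch_sites, paste, collapse = ",",
                      FUN.VALUE = character(1)),
    stringsAsFactors = FALSE)
  write.table(side, paste0(path, ".branches.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTA file as a DNAStringSet
#' @param path FASTA path.
#' @return a `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Run configuration
#'
#' A named list of stage parameters, seeds and paths that round-trips
#' losslessly through JSON.
#'
#' @param ... named configuration entries.
#' @return list of class `msy_config`.
#' @export
msy_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) && is.null(names(cfg))) stop("config entries must be named")
  structure(cfg, class = "msy_config")
}

#' @rdname msy_config
#' @param path JSON path.
#' @export
read_config <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "msy_config")
}

#' @rdname msy_config
#' @param cfg an `msy_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
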