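# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures.

# Compact variant_set builder: `gt` is a variants x samples character
# matrix with entries ref/alt/het/missing; scalar dp/gq/phased recycle.
make_vs <- function(gt, contig = "ctg1", pos = seq_len(nrow(gt)) * 100L,
                    ref = "A", alt = "G", marker_type = "SNV",
                    dp = 10L, gq = 99L, phased = FALSE,
                    ids = sprintf("var%03d", seq_len(nrow(gt)))) {
  n <- nrow(gt); m <- ncol(gt)
  expand <- function(x, mode) {
    out <- matrix(rep_len(x, n * m), n, m, dimnames = dimnames(gt))
    mode(out) <- mode
    out
  }
  meta <- data.frame(id = ids, contig = rep_len(contig, n),
                     pos = as.integer(pos), ref = rep_len(ref, n),
                     alt = rep_len(alt, n),
                     marker_type = rep_len(marker_type, n),
                     stringsAsFactors = FALSE)
  variant_set(meta, gt, expand(dp, "integer"), expand(gq, "integer"),
              expand(phased, "logical"))
}

gt_matrix <- function(rows, samples) {
  m <- do.call(rbind, rows)
  colnames(m) <- samples
  m
}

scy_granges <- function(contig = "ctg1", start1 = 1L, end = 10000L) {
  GenomicRanges::GRanges(contig, IRanges::IRanges(start = start1, end = end))
}

# Polarized haplo_matrix from a 0/1/NA matrix plus an implicit
# all-ancestral outgroup row.
hm <- function(states, samples = rownames(states), outgroup = "OUT") {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(states)))
  S <- rbind(states, 0L)
  rownames(S) <- c(samples, outgroup)
  if (is.null(colnames(S))) colnames(S) <- paste0("v", seq_len(ncol(S)))
  haplo_matrix(S, outgroup, polarized = TRUE)
}

# Literal transcription of the two-model Poisson likelihood ratio with
# factorial terms included on both sides (independent oracle for
# window_log_lr). Requires integer y.
log_lr_literal <- function(y, profiles) {
  male <- profiles$sex == "male"
  ym <- y[profiles$sample_id[male]]; yf <- y[profiles$sample_id[!male]]
  cm <- profiles$c[male]; cf <- profiles$c[!male]; b <- profiles$b[!male]
  v <- sum(ym) / sum(cm / 2)
  mu <- sum(c(ym, yf)) / sum(c(cm, cf))
  num <- sum(dpois(ym, v * cm / 2, log = TRUE)) +
    sum(dpois(yf, b, log = TRUE))
  den <- sum(dpois(ym, mu * cm, log = TRUE)) +
    sum(dpois(yf, mu * cf, log = TRUE))
  num - den
}

# Tiny uncompressed VCF written to a temp file; returns the path.
write_tiny_vcf <- function(records, samples = c("S1", "S2", "S3"),
                           format = "GT:DP:GQ") {
  path <- tempfile(fileext = ".vcf")
  fmt_lines <- c(
    GT = '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    DP = '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    GQ = '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">')
  contigs <- unique(vapply(strsplit(records, "\t"), `[`, character(1), 1))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=100000>", contigs),
    unname(fmt_lines[strsplit(format, ":")[[1]]]),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_rec <- function(chrom, pos, id, ref, alt, calls,
                    format = "GT:DP:GQ") {
  paste(c(chrom, pos, id, ref, alt, ".", ".", ".", format, calls),
        collapse = "\t")
}
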