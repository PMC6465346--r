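# Haplotype matrix, perfect phylogeny under the infinite-sites model,
# exhaustive maximum-parsimony oracle, and flank-based liftover.

#' Construct a haplotype matrix
#'
#' Samples-by-sites matrix of allelic states: before polarization 0/1
#' code reference/alternate; after [polarize()], 0 is ancestral and 1
#' derived. `NA` codes missing (including heterozygous calls on the
#' haploid Y).
#'
#' @param states integer matrix, rows named by sample, columns by
#'   variant id; entries 0, 1 or `NA`.
#' @param outgroup_id row name of the outgroup sample.
#' @param polarized logical; `TRUE` once states are ancestral/derived.
#' @return object of class `haplo_matrix`.
#' @export
haplo_matrix <- function(states, outgroup_id, polarized = FALSE) {
  states <- as.matrix(states)
  mode(states) <- "integer"
  stopifnot(!is.null(rownames(states)),
            all(states %in% c(0L, 1L, NA_integer_)))
  if (!outgroup_id %in% rownames(states))
    stop("outgroup sample not present in matrix: ", outgroup_id)
  if (ncol(states) > 0 && is.null(colnames(states)))
    colnames(states) <- paste0("v", seq_len(ncol(states)))
  all_missing_col <- ncol(states) > 0 & colSums(!is.na(states)) == 0
  if (any(all_missing_col))
    stop("all-missing site column(s): ",
         paste(colnames(states)[all_missing_col], collapse = ", "))
  structure(states, class = "haplo_matrix",
            outgroup_id = outgroup_id, polarized = polarized)
}

#' Extract the bare state matrix from a haplo_matrix
#' @param mat a [haplo_matrix()].
#' @return plain integer matrix (0/1/`NA`) without class attributes.
#' @export
unclass_states <- function(mat) {
  s <- unclass(mat)
  attr(s, "outgroup_id") <- NULL
  attr(s, "polarized") <- NULL
  s
}

#' @export
print.haplo_matrix <- function(x, ...) {
  cat("haplo_matrix:", nrow(x), "samples x", ncol(x), "sites; outgroup",
      attr(x, "outgroup_id"),
      if (isTRUE(attr(x, "polarized"))) "(polarized)\n" else "(unpolarized)\n")
  invisible(x)
}

#' Build a haplotype matrix from a filtered variant set
#'
#' Maps categorical genotypes to allelic states: `ref` to 0, `alt` to 1,
#' `het` and `missing` to `NA` (heterozygous calls on the haploid Y are
#' unreliable). Sites that end up all-missing are dropped.
#'
#' @param x a [variant_set()].
#' @param outgroup_id sample id to designate as outgroup.
#' @return an unpolarized [haplo_matrix()].
#' @export
as_haplo_matrix <- function(x, outgroup_id) {
  stopifnot(inherits(x, "variant_set"))
  S <- matrix(NA_integer_, ncol(x$gt), nrow(x$meta),
              dimnames = list(colnames(x$gt), x$meta$id))
  S[t(x$gt) == "ref"] <- 0L
  S[t(x$gt) == "alt"] <- 1L
  keep <- colSums(!is.na(S)) > 0
  if (!all(keep))
    warning(sum(!keep), " all-missing site(s) dropped")
  haplo_matrix(S[, keep, drop = FALSE], outgroup_id)
}

#' Polarize a haplotype matrix against the outgroup
#'
#' Recodes states so the outgroup reads ancestral (0) at every retained
#' site. Sites where the outgroup is missing fall back to
#' `secondary_outgroup_id` when given; sites with no informative
#' outgroup state are dropped with a warning.
#'
#' @param mat a [haplo_matrix()].
#' @param outgroup_id primary outgroup sample (defaults to the matrix's
#'   designated outgroup).
#' @param secondary_outgroup_id optional fallback outgroup.
#' @return a polarized `haplo_matrix`.
#' @export
polarize <- function(mat, outgroup_id = attr(mat, "outgroup_id"),
                     secondary_outgroup_id = NULL) {
  stopifnot(inherits(mat, "haplo_matrix"))
  S <- unclass_states(mat)
  if (!outgroup_id %in% rownames(S))
    stop("no outgroup row: ", outgroup_id)
  anc <- S[outgroup_id, ]
  if (!is.null(secondary_outgroup_id)) {
    fall <- is.na(anc)
    anc[fall] <- S[secondary_outgroup_id, fall]
  }
  drop <- is.na(anc)
  if (any(drop)) {
    warning(sum(drop), " site(s) with no informative outgroup state dropped: ",
            paste(utils::head(colnames(S)[drop], 5), collapse = ", "),
            if (sum(drop) > 5) ", ...")
    S <- S[, !drop, drop = FALSE]
    anc <- anc[!drop]
  }
  flip <- which(anc == 1L)
  S[, flip] <- 1L - S[, flip]
  haplo_matrix(S, outgroup_id = outgroup_id, polarized = TRUE)
}

#' Collapse samples into haplotypes
#'
#' Partitions samples into maximal groups whose non-missing states agree
#' at every site; missing entries are compatible with any state. The
#' partition is made deterministic by greedy assignment in sample order:
#' each sample joins the first existing group whose running consensus it
#' matches, refining that consensus with its own non-missing states.
#' Haplotype ids are `H1`, `H2`, ... in first-member order.
#'
#' @param mat a polarized [haplo_matrix()].
#' @return list with `haplotypes` (named list: haplotype id ->
#'   member sample ids) and `consensus` (haplotypes x sites state
#'   matrix; residual `NA` where no member is informative).
#' @export
collapse_haplotypes <- function(mat) {
  stopifnot(inherits(mat, "haplo_matrix"))
  S <- unclass_states(mat)
  groups <- list()       # member indices
  consensus <- list()    # running consensus state vectors
  for (i in seq_len(nrow(S))) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      cons <- consensus[[g]]
      ok <- !is.na(cons) & !is.na(S[i, ])
      if (all(cons[ok] == S[i, ok])) {
        fill <- is.na(cons) & !is.na(S[i, ])
        cons[fill] <- S[i, fill]
        consensus[[g]] <- cons
        groups[[g]] <- c(groups[[g]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      groups[[length(groups) + 1L]] <- i
      consensus[[length(consensus) + 1L]] <- S[i, ]
    }
  }
  ids <- paste0("H", seq_along(groups))
  haps <- setNames(lapply(groups, function(g) rownames(S)[g]), ids)
  cons <- do.call(rbind, consensus)
  rownames(cons) <- ids
  colnames(cons) <- colnames(S)
  list(haplotypes = haps, consensus = cons)
}

#' Four-gamete test over all site pairs
#'
#' Under the infinite-sites model every site mutated exactly once, so no
#' pair of sites can show all four gametes 00, 01, 10, 11 among
#' non-missing rows. Missing entries are wildcards (never witness a
#' gamete).
#'
#' @param mat a polarized [haplo_matrix()].
#' @return list with `compatible` (logical) and `incompatible_pairs`
#'   (data.frame `site1`, `site2`).
#' @export
four_gamete_check <- function(mat) {
  stopifnot(inherits(mat, "haplo_matrix"))
  S <- unclass_states(mat)
  if (ncol(S) < 2)
    return(list(compatible = TRUE,
                incompatible_pairs = data.frame(site1 = character(),
                                                site2 = character())))
  X1 <- (S == 1L); X1[is.na(X1)] <- FALSE; mode(X1) <- "numeric"
  X0 <- (S == 0L); X0[is.na(X0)] <- FALSE; mode(X0) <- "numeric"
  n11 <- crossprod(X1) > 0
  n00 <- crossprod(X0) > 0
  n10 <- crossprod(X1, X0) > 0
  n01 <- crossprod(X0, X1) > 0
  bad <- n11 & n00 & n10 & n01
  bad[lower.tri(bad, diag = TRUE)] <- FALSE
  idx <- which(bad, arr.ind = TRUE)
  pairs <- data.frame(site1 = colnames(S)[idx[, 1]],
                      site2 = colnames(S)[idx[, 2]],
                      stringsAsFactors = FALSE)
  list(compatible = nrow(pairs) == 0, incompatible_pairs = pairs)
}

#' Build the perfect phylogeny of a compatible haplotype matrix
#'
#' Samples are first collapsed into haplotypes; sites with identical
#' derived haplotype sets stack on one branch; the laminar family of
#' derived sets then defines the unique rooted tree (up to ordering of
#' branches with identical support). The root is the outgroup-anchored
#' ancestral state; branches without a supporting mutation exist only at
#' leaves, so unresolved splits appear as polytomies. Residual missing
#' states in a haplotype consensus are treated as ancestral with a
#' warning.
#'
#' @param mat a polarized [haplo_matrix()].
#' @return object of class `clade_tree`: a list with `edges`
#'   (data.frame `parent`, `child`, `mutations`), `branch_sites` (named
#'   list: child node -> variant ids on the branch into it),
#'   `haplotypes` (haplotype id -> member samples), `leaves` (leaf node
#'   names), `outgroup` (the haplotype containing the outgroup sample)
#'   and `n_sites`.
#' @export
build_perfect_phylogeny <- function(mat) {
  stopifnot(inherits(mat, "haplo_matrix"))
  if (!isTRUE(attr(mat, "polarized")))
    stop("matrix must be polarized before tree building; see polarize()")
  fg <- four_gamete_check(mat)
  if (!fg$compatible)
    stop("matrix violates the infinite-sites model; incompatible site pairs: ",
         paste(fg$incompatible_pairs$site1, fg$incompatible_pairs$site2,
               sep = "/", collapse = ", "))
  coll <- collapse_haplotypes(mat)
  H <- coll$consensus
  if (anyNA(H)) {
    warning(sum(is.na(H)), " unresolved state(s) treated as ancestral")
    H[is.na(H)] <- 0L
  }
  og_hap <- names(coll$haplotypes)[vapply(coll$haplotypes, function(m)
    attr(mat, "outgroup_id") %in% m, logical(1))]
  if (any(H[og_hap, ] == 1L))
    stop("outgroup haplotype carries derived states; matrix not polarized?")

  n_hap <- nrow(H)
  hap_ids <- rownames(H)
  # derived set per site as a signature over haplotypes
  sig <- apply(H, 2, paste, collapse = "")
  site_sets <- split(colnames(H), sig)
  set_masks <- lapply(names(site_sets), function(s)
    as.integer(strsplit(s, "")[[1]]) == 1L)
  nonempty <- vapply(set_masks, any, logical(1))
  if (any(!nonempty)) {
    # sites derived nowhere cannot arise after polarization + all-missing
    # pruning, but guard anyway
    site_sets <- site_sets[nonempty]
    set_masks <- set_masks[nonempty]
  }

  # node universe: root (all), mutation-supported sets, haplotype leaves
  masks <- set_masks
  mut_sites <- site_sets
  leaf_masks <- lapply(seq_len(n_hap), function(i) seq_len(n_hap) == i)
  keys <- vapply(masks, function(m) paste(as.integer(m), collapse = ""),
                 character(1))
  leaf_keys <- vapply(leaf_masks, function(m)
    paste(as.integer(m), collapse = ""), character(1))
  for (i in seq_len(n_hap)) {
    if (!leaf_keys[i] %in% keys) {
      masks[[length(masks) + 1L]] <- leaf_masks[[i]]
      mut_sites[[length(mut_sites) + 1L]] <- character(0)
      keys <- c(keys, leaf_keys[i])
    }
  }
  root_key <- paste(rep(1L, n_hap), collapse = "")
  if (!root_key %in% keys) {
    masks[[length(masks) + 1L]] <- rep(TRUE, n_hap)
    mut_sites[[length(mut_sites) + 1L]] <- character(0)
    keys <- c(keys, root_key)
  }

  sizes <- vapply(masks, sum, integer(1))
  node_names <- ifelse(sizes == 1,
                       hap_ids[vapply(masks, which.max, integer(1))],
                       ifelse(keys == root_key, "root",
                              paste0("n", seq_along(masks))))
  # laminar check (redundant with four-gamete on complete data, but the
  # consensus NA->0 fill could in principle break it): every pair of
  # derived sets must be nested or disjoint
  if (length(set_masks) > 1) {
    for (a in seq_len(length(set_masks) - 1L))
      for (b in seq(a + 1L, length(set_masks))) {
        A <- set_masks[[a]]; B <- set_masks[[b]]
        if (any(A & B) && !(all(!B | A) || all(!A | B)))
          stop("derived sets are not laminar; matrix incompatible")
      }
  }

  # parent = smallest strict superset
  parent <- integer(length(masks))
  for (i in seq_along(masks)) {
    if (keys[i] == root_key) { parent[i] <- NA_integer_; next }
    sup <- which(vapply(masks, function(m)
      all(!masks[[i]] | m) && sum(m) > sizes[i], logical(1)))
    parent[i] <- sup[which.min(sizes[sup])]
  }

  edges <- data.frame(parent = node_names[parent],
                      child = node_names,
                      mutations = lengths(mut_sites),
                      stringsAsFactors = FALSE)
  edges <- edges[!is.na(parent), , drop = FALSE]
  rownames(edges) <- NULL
  branch_sites <- setNames(mut_sites, node_names)
  branch_sites <- branch_sites[edges$child]

  structure(list(edges = edges, branch_sites = branch_sites,
                 haplotypes = coll$haplotypes,
                 leaves = node_names[sizes == 1],
                 outgroup = og_hap, n_sites = ncol(H)),
            class = "clade_tree")
}

#' @export
print.clade_tree <- function(x, ...) {
  cat("clade_tree:", length(x$leaves), "haplotype leaves,",
      nrow(x$edges), "branches,", x$n_sites, "mutations\n")
  invisible(x)
}

#' Total tree length (number of mutations)
#' @param tree a `clade_tree`.
#' @return integer tree length.
#' @export
tree_length <- function(tree) sum(tree$edges$mutations)

#' Per-branch mutation counts
#'
#' @param tree a `clade_tree` from [build_perfect_phylogeny()].
#' @return named integer vector, one entry per branch keyed by its child
#'   node; entries sum to the number of sites.
#' @export
branch_mutation_counts <- function(tree) {
  stopifnot(inherits(tree, "clade_tree"))
  setNames(tree$edges$mutations, tree$edges$child)
}

#' Convert a clade tree to an ape phylo object
#'
#' Branch lengths carry mutation counts; haplotype leaves become tips.
#'
#' @param tree a `clade_tree`.
#' @return an [ape::phylo] object.
#' @export
as_phylo <- function(tree) {
  stopifnot(inherits(tree, "clade_tree"))
  tips <- tree$leaves
  internals <- setdiff(unique(c(tree$edges$parent, tree$edges$child)), tips)
  internals <- c("root", setdiff(internals, "root"))
  idx <- setNames(seq_along(c(tips, internals)), c(tips, internals))
  edge <- cbind(idx[tree$edges$parent], idx[tree$edges$child])
  dimnames(edge) <- NULL
  phy <- list(edge = edge, tip.label = tips,
              edge.length = as.numeric(tree$edges$mutations),
              Nnode = length(internals),
              node.label = internals)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

#' Exhaustive maximum-parsimony length (test oracle)
#'
#' Minimum Fitch parsimony length over all unrooted binary topologies;
#' intended as an independent oracle for small matrices. Missing states
#' enter as full ambiguity.
#'
#' @param mat a [haplo_matrix()] with at most 8 samples.
#' @return integer minimum parsimony length.
#' @export
mp_length_exhaustive <- function(mat) {
  stopifnot(inherits(mat, "haplo_matrix"))
  S <- unclass_states(mat)
  n <- nrow(S)
  if (n > 8) stop("exhaustive search limited to 8 taxa")
  ch <- matrix(as.character(S), nrow(S), dimnames = dimnames(S))
  ch[is.na(ch)] <- "?"
  if (n == 2) {
    ok <- ch[1, ] != "?" & ch[2, ] != "?"
    return(sum(ch[1, ok] != ch[2, ok]))
  }
  dat <- phangorn::phyDat(ch, type = "USER", levels = c("0", "1"),
                          ambiguity = "?")
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = rownames(S))
  min(phangorn::parsimony(trees, dat, method = "fitch"))
}

#' Site-resampling bootstrap support for clades
#'
#' Resamples matrix columns with replacement, rebuilds the perfect
#' phylogeny and reports, for every internal clade of the original tree,
#' the fraction of replicates whose tree contains a clade with the same
#' sample membership.
#'
#' @param mat a polarized, compatible [haplo_matrix()].
#' @param n_reps number of bootstrap replicates.
#' @param seed RNG seed.
#' @return named numeric vector of support fractions keyed by internal
#'   node name of the original tree.
#' @export
bootstrap_support <- function(mat, n_reps = 100L, seed = 1L) {
  tree <- build_perfect_phylogeny(mat)
  clade_members <- function(tr) {
    kids <- split(tr$edges$child, tr$edges$parent)
    below <- function(node) {
      if (!node %in% names(kids)) return(tr$haplotypes[[node]])
      unlist(lapply(kids[[node]], below), use.names = FALSE)
    }
    internals <- setdiff(unique(tr$edges$parent), "root")
    setNames(lapply(internals, function(nd) sort(below(nd))), internals)
  }
  orig <- clade_members(tree)
  if (length(orig) == 0) return(setNames(numeric(0), character(0)))
  S <- unclass_states(mat)
  hits <- setNames(numeric(length(orig)), names(orig))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol(S), replace = TRUE)
      Sb <- S[, cols, drop = FALSE]
      colnames(Sb) <- paste0(colnames(S)[cols], "_", seq_along(cols))
      tb <- build_perfect_phylogeny(
        haplo_matrix(Sb, attr(mat, "outgroup_id"), polarized = TRUE))
      sets <- unique(vapply(clade_members(tb), paste, collapse = "|",
                            FUN.VALUE = character(1)))
      keys <- vapply(orig, paste, collapse = "|", FUN.VALUE = character(1))
      hits <- hits + (keys %in% sets)
    }
  })
  hits / n_reps
}

#' STR allele length from repeat-count difference
#'
#' Microsatellite alleles are scored as amplicon lengths: a derived
#' allele differing by `repeat_diff` repeat units from the reference has
#' length `ref_len + unit_len * repeat_diff`.
#'
#' @param ref_len reference amplicon length in bp.
#' @param unit_len repeat unit length in bp (4 for a tetranucleotide).
#' @param repeat_diff derived minus reference repeat count.
#' @return allele length in bp.
#' @examples
#' str_allele_length(204, 4, 1)  # one extra GATA repeat -> 208
#' @export
str_allele_length <- function(ref_len, unit_len, repeat_diff) {
  stopifnot(ref_len > 0, unit_len > 0)
  ref_len + unit_len * repeat_diff
}

#' Lift a variant onto a target assembly by exact flank match
#'
#' Searches both strands of the target for an exact occurrence of
#' `left_flank + <gap> + right_flank`, where the gap width equals the
#' variant length. Status is `unique` for exactly one occurrence (the
#' 1-based gap-start coordinate on the forward strand is reported),
#' `absent` for none and `ambiguous` for several; mismatch-tolerant
#' rescue is out of scope.
#'
#' @param left_flank,right_flank character or `DNAString` flanking
#'   sequences (non-empty; 50 bp each is typical).
#' @param gap_len variant length in bp (1 for an SNV).
#' @param target a named `DNAStringSet` (or named character vector) of
#'   target contigs.
#' @return list with `status`, and for unique hits `contig`, `pos`
#'   (1-based gap start) and `strand`.
#' @export
liftover_by_flank <- function(left_flank, right_flank, gap_len, target) {
  if (!methods::is(target, "DNAStringSet"))
    target <- Biostrings::DNAStringSet(target)
  if (is.null(names(target))) stop("target contigs must be named")
  left <- Biostrings::DNAString(as.character(left_flank))
  right <- Biostrings::DNAString(as.character(right_flank))
  if (length(left) == 0 || length(right) == 0)
    stop("flanks must be non-empty")
  stopifnot(gap_len >= 0)

  scan <- function(L, R, strand) {
    hits <- list()
    for (ctg in names(target)) {
      subj <- target[[ctg]]
      m <- Biostrings::matchPattern(L, subj)
      for (s in Biostrings::start(m)) {
        g <- s + length(L)            # gap start
        r <- g + gap_len              # right flank start
        if (r + length(R) - 1 > length(subj)) next
        if (as.character(Biostrings::subseq(subj, r, r + length(R) - 1)) ==
            as.character(R))
          hits[[length(hits) + 1L]] <-
            data.frame(contig = ctg, pos = g, strand = strand,
                       stringsAsFactors = FALSE)
      }
    }
    hits
  }
  fwd <- scan(left, right, "+")
  rev <- scan(Biostrings::reverseComplement(right),
              Biostrings::reverseComplement(left), "-")
  hits <- do.call(rbind, c(fwd, rev))
  if (is.null(hits) || nrow(hits) == 0)
    return(list(status = "absent", contig = NA_character_,
                pos = NA_integer_, strand = NA_character_))
  if (nrow(hits) > 1)
    return(list(status = "ambiguous", contig = NA_character_,
                pos = NA_integer_, strand = NA_character_))
  list(status = "unique", contig = hits$contig, pos = as.integer(hits$pos),
       strand = hits$strand)
}
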