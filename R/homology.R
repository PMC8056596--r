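# Protein homology: pairwise global-alignment percent identity, identity
# profile correlations, hierarchical family grouping, candidate expansion.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Read protein sequences from FASTA
#'
#' @param path FASTA file (plain or aligned; gap characters are kept).
#' @return named character vector of uppercase sequences.
#' @export
read_fasta_seqs <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(s))
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

check_seqset <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  empty <- names(seqs)[nchar(seqs) == 0]
  if (length(empty) > 0)
    stop("empty sequence(s): ", paste(empty, collapse = ", "))
  invisible(toupper(seqs))
}

#' Pairwise percent identity by global alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties for every
#' sequence pair (via Biostrings), scoring `match` for identities and
#' `mismatch` otherwise; a gap of length L scores `gap_open + L *
#' gap_extend`. Identity is the number of identical aligned columns divided
#' by the total number of alignment columns (gap columns included), times
#' 100. The denominator is configurable: `denominator = "shorter"` divides
#' by the shorter sequence length instead.
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param match,mismatch,gap_open,gap_extend alignment scoring parameters
#'   (penalties negative).
#' @param denominator `"columns"` (default) or `"shorter"`.
#' @return symmetric matrix of percent identities, diagonal 100.
#' @export
pairwise_identity <- function(seqs, match = 1, mismatch = 0,
                              gap_open = -5, gap_extend = -1,
                              denominator = c("columns", "shorter")) {
  seqs <- check_seqset(seqs)
  denominator <- match.arg(denominator)
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences")
  nms <- sort(names(seqs))
  seqs <- seqs[nms]
  sub_mat <- matrix(mismatch, length(AA_ALPHABET), length(AA_ALPHABET),
                    dimnames = list(AA_ALPHABET, AA_ALPHABET))
  diag(sub_mat) <- match
  idm <- matrix(100, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      aln <- Biostrings::pairwiseAlignment(
        seqs[[i]], seqs[[j]], type = "global",
        substitutionMatrix = sub_mat,
        gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
      a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
      b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
      nmatch <- sum(a == b & a != "-")
      den <- if (denominator == "columns") length(a) else
        min(nchar(seqs[[i]]), nchar(seqs[[j]]))
      idm[i, j] <- idm[j, i] <- 100 * nmatch / den
    }
  }
  idm
}

#' Percent identity from a precomputed aligned FASTA
#'
#' Alternative entry into the identity matrix: all sequences already share
#' alignment coordinates (equal lengths, `-` for gaps). Identity per pair is
#' identical non-gap columns over all columns where at least one sequence
#' has a residue.
#'
#' @param aligned named character vector of equal-length aligned sequences.
#' @return symmetric percent-identity matrix.
#' @export
identity_from_alignment <- function(aligned) {
  aligned <- check_seqset(aligned)
  if (length(unique(nchar(aligned))) != 1)
    stop("aligned sequences must have equal length")
  nms <- sort(names(aligned))
  aligned <- aligned[nms]
  chars <- do.call(rbind, strsplit(aligned, ""))
  n <- length(aligned)
  idm <- matrix(100, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- chars[i, ]; b <- chars[j, ]
      keep <- !(a == "-" & b == "-")
      idm[i, j] <- idm[j, i] <- 100 * sum(a[keep] == b[keep] &
                                            a[keep] != "-") / sum(keep)
    }
  }
  idm
}

#' Correlation of identity profiles
#'
#' Pearson correlation between rows of the identity matrix. For a pair
#' (i, j) the self-entries of the two genes (columns i and j) are excluded,
#' so the correlation reflects how similarly the two proteins relate to the
#' rest of the family. Zero-variance profiles give `NA` with a warning-free
#' flag in the result attributes.
#'
#' @param idm square percent-identity matrix with dimnames.
#' @return correlation matrix with unit diagonal; attribute `undefined`
#'   lists pairs with zero-variance profiles.
#' @export
profile_correlation <- function(idm) {
  n <- nrow(idm)
  if (n < 3) stop("need at least 3 sequences for profile correlations")
  if (!isTRUE(all.equal(idm, t(idm), check.attributes = FALSE)))
    stop("identity matrix must be symmetric")
  cm <- matrix(1, n, n, dimnames = dimnames(idm))
  undefined <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      keep <- setdiff(seq_len(n), c(i, j))
      xi <- idm[i, keep]; xj <- idm[j, keep]
      if (sd(xi) == 0 || sd(xj) == 0) {
        cm[i, j] <- cm[j, i] <- NA_real_
        undefined <- c(undefined,
                       paste(rownames(idm)[i], rownames(idm)[j], sep = ":"))
      } else {
        cm[i, j] <- cm[j, i] <- cor(xi, xj)
      }
    }
  }
  attr(cm, "undefined") <- undefined
  cm
}

#' Cluster proteins into homology groups
#'
#' Average-linkage hierarchical clustering on distance 1 - R (profile
#' correlation, default) or 1 - identity/100 (`use = "identity"`). Groups by
#' cutting the tree at height `cut` or into `k` groups. Genes are ordered by
#' name before linkage so the dendrogram is deterministic.
#'
#' @param mat correlation matrix (R in \[-1, 1\]) or identity matrix
#'   (percent), per `use`.
#' @param use `"correlation"` (default) or `"identity"`.
#' @param cut tree-cut height on the distance scale (ignored when `k` set).
#' @param k number of groups (optional).
#' @param method linkage method (default `"average"`).
#' @return list with `groups` (named integer vector), `hclust` (the tree),
#'   `n_groups`.
#' @export
cluster_groups <- function(mat, use = c("correlation", "identity"),
                           cut = NULL, k = NULL, method = "average") {
  use <- match.arg(use)
  ord <- order(rownames(mat))
  mat <- mat[ord, ord]
  d <- if (use == "correlation") 1 - mat else 1 - mat / 100
  if (anyNA(d)) stop("distance matrix contains undefined entries")
  hc <- hclust(as.dist(d), method = method)
  if (!is.null(k)) {
    if (k > nrow(mat)) stop("k exceeds the number of sequences")
    grp <- cutree(hc, k = k)
  } else if (!is.null(cut)) {
    grp <- cutree(hc, h = cut)
  } else {
    stop("supply either cut or k")
  }
  list(groups = grp, hclust = hc, n_groups = length(unique(grp)))
}

#' Export a homology dendrogram as newick
#'
#' @param hc an `hclust` object (from [cluster_groups()]).
#' @param path output file.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Expand candidate genes by homology-group membership
#'
#' Every member of a group containing at least one known NDD gene becomes a
#' candidate (the family-expansion step: paralogs of implicated genes are
#' candidates even without published cases).
#'
#' @param groups named group vector (from [cluster_groups()]`$groups`).
#' @param known_ndd character vector of known NDD genes (must be a subset of
#'   the grouped gene names).
#' @return sorted character vector of candidate genes.
#' @export
expand_candidates <- function(groups, known_ndd) {
  grp <- if (is.list(groups)) groups$groups else groups
  missing <- setdiff(known_ndd, names(grp))
  if (length(missing) > 0)
    stop("known NDD gene(s) not among sequences: ",
         paste(missing, collapse = ", "))
  hit <- unique(grp[known_ndd])
  sort(names(grp)[grp %in% hit])
}

#' Write a square matrix as TSV
#' @param m matrix with dimnames.
#' @param path output file.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(name = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
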