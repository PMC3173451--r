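# Pairwise protein distances and the built-in neighbor-joining backend.
#
# Distances use pairwise deletion: a column enters the comparison of a pair
# only when neither sequence has a gap there, which keeps short environmental
# fragments usable against full-length reference sequences.

#' Pairwise distance matrix from a protein alignment
#'
#' `p` is the mismatch fraction over compared columns; `poisson` is the
#' Poisson correction \eqn{-\ln(1-p)}; `f81` is the composition-aware
#' correction \eqn{-b\,\ln(1-p/b)} with \eqn{b = 1-\sum_a \hat\pi_a^2}
#' estimated from the pooled residue frequencies (the protein analogue of
#' the Tajima-Nei distance, exact for an equal-input substitution process
#' and less biased than Poisson at deep divergences).
#'
#' @param aln alignment matrix or named sequence strings
#' @param model `"p"`, `"poisson"` or `"f81"`
#' @return symmetric numeric matrix with zero diagonal, dimnames = sequence
#'   ids (substitutions/site under the corrected models)
#' @export
pairwise_distance <- function(aln, model = c("poisson", "p", "f81")) {
  model <- match.arg(model)
  m <- as_alignment_matrix(aln)
  m[m %in% GAP_CHARS] <- NA_character_
  valid <- !is.na(m)
  comparable <- tcrossprod(valid + 0)
  if (any(comparable[upper.tri(comparable)] == 0)) {
    bad <- which(comparable == 0 & upper.tri(comparable), arr.ind = TRUE)[1L, ]
    stop(sprintf("no comparable columns between '%s' and '%s'",
                 rownames(m)[bad[1L]], rownames(m)[bad[2L]]))
  }
  matches <- matrix(0, nrow(m), nrow(m))
  for (a in unique(m[valid])) {
    B <- (m == a) & valid
    matches <- matches + tcrossprod(B + 0)
  }
  p <- 1 - matches / comparable
  diag(p) <- 0
  p[p < 0] <- 0
  dimnames(p) <- list(rownames(m), rownames(m))
  if (model == "p") return(p)
  if (model == "poisson") {
    if (any(p[upper.tri(p)] >= 1)) {
      stop("p = 1 between some pair: the Poisson distance -ln(1-p) is undefined")
    }
    d <- -log(1 - p)
  } else {
    freqs <- table(m[valid]) / sum(valid)
    b <- 1 - sum(freqs^2)
    if (any(p[upper.tri(p)] >= b)) {
      stop(sprintf("p >= b = %.3f between some pair: the corrected distance is undefined (saturated)",
                   b))
    }
    d <- -b * log(1 - p / b)
  }
  diag(d) <- 0
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Wraps the classical NJ agglomeration; negative estimated branch lengths
#' are clamped to zero, and zero-length internal branches are collapsed to
#' polytomies. Labels are ordered lexicographically before agglomeration so
#' the result does not depend on input row order.
#'
#' @param dm symmetric non-negative matrix with dimnames (or `dist`)
#' @return unrooted `phylo`
#' @export
neighbor_joining <- function(dm) {
  m <- as.matrix(dm)
  labs <- rownames(m)
  if (is.null(labs)) stop("distance matrix must have row/column names")
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 labels")
  if (!isSymmetric(unname(m), tol = 1e-8)) {
    stop("distance matrix is not symmetric")
  }
  if (any(m < 0)) stop("distances must be non-negative")
  ord <- order(labs)
  m <- m[ord, ord]
  tr <- ape::nj(m)
  if (!is.null(tr$edge.length)) {
    tr$edge.length[tr$edge.length < 0] <- 0
    tr <- ape::di2multi(tr, tol = 1e-12)
  }
  tr
}

#' Tree-inference backend based on NJ over pairwise distances
#'
#' Returns a function mapping an alignment matrix to an unrooted `phylo`;
#' any engine with the same signature (alignment in, tree out) can replace
#' it in [run_screen()].
#'
#' @param model distance model, see [pairwise_distance()]
#' @export
nj_backend <- function(model = "poisson") {
  force(model)
  function(aln) neighbor_joining(pairwise_distance(aln, model = model))
}
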