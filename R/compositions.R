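#' @useDynLib polypcomp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rmultinom qnorm qlogis plogis quantile sd var
#'   optim rWishart qt rgamma acf setNames simulate
#' @importFrom utils read.csv write.csv head tail
NULL

# tolerance used for closure / orthonormality validation throughout
.closure_tol <- 1e-12

#' Close a vector of nonnegative amounts to a composition
#'
#' Divides each part by the total so that the result lies on the unit simplex.
#' All relative information (ratios of parts) is preserved.
#'
#' @param x numeric vector (or matrix with one composition per row) of
#'   nonnegative amounts, at least one positive.
#' @return numeric vector (or matrix) of proportions summing to 1.
#' @export
#' @examples
#' close_comp(c(3, 1, 1))
close_comp <- function(x) {
  if (is.matrix(x)) {
    if (any(!is.finite(x)) || any(x < 0)) stop("amounts must be finite and nonnegative")
    tot <- rowSums(x)
    if (any(tot <= 0)) stop("each row must have a positive total")
    return(x / tot)
  }
  if (any(!is.finite(x)) || any(x < 0)) stop("amounts must be finite and nonnegative")
  tot <- sum(x)
  if (tot <= 0) stop("at least one part must be positive")
  x / tot
}

#' Replace zero counts before logratio analysis
#'
#' Zero counts are replaced by a small positive value (1/2 of a count by
#' default) and the result is closed. Used only for display (ternary plots of
#' observed counts); model likelihoods act on the raw counts and never need
#' imputation.
#'
#' @param counts nonnegative integer vector of point counts.
#' @param replacement positive value substituted for each zero count.
#' @return closed composition.
#' @export
zero_replace <- function(counts, replacement = 0.5) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (all(counts == 0)) stop("all-zero counts cannot form a composition")
  if (!is.finite(replacement) || replacement <= 0) stop("replacement must be positive")
  counts[counts == 0] <- replacement
  close_comp(counts)
}

#' Orthonormal basis from a sequential binary partition
#'
#' Builds the (D-1) x D contrast matrix of balances for a sequential binary
#' partition of the parts. Row i has coefficient +sqrt(s/(r(r+s))) on the r
#' parts in the numerator group and -sqrt(r/(s(r+s))) on the s parts in the
#' denominator group. Rows are orthonormal and sum to zero, so the matrix maps
#' centred logratios to isometric logratio (ilr) coordinates.
#'
#' @param partition list of length D-1; each element a list or pair of two
#'   integer vectors (numerator indices, denominator indices).
#' @param D number of parts.
#' @param labels optional character descriptions of each balance.
#' @return object of class `contrast_matrix`: the matrix with attributes
#'   `partition` and `labels`.
#' @export
sbp_basis <- function(partition, D, labels = NULL) {
  if (length(partition) != D - 1L) stop("need D-1 binary partitions")
  V <- matrix(0, D - 1L, D)
  for (i in seq_along(partition)) {
    num <- partition[[i]][[1]]
    den <- partition[[i]][[2]]
    if (length(intersect(num, den)) > 0L || any(c(num, den) < 1L) || any(c(num, den) > D))
      stop("invalid partition at row ", i)
    r <- length(num); s <- length(den)
    V[i, num] <- sqrt(s / (r * (r + s)))
    V[i, den] <- -sqrt(r / (s * (r + s)))
  }
  G <- V %*% t(V)
  if (max(abs(G - diag(D - 1L))) > .closure_tol * 100)
    stop("partition does not give an orthonormal basis")
  structure(V, class = "contrast_matrix", partition = partition,
            labels = labels %||% paste0("balance_", seq_len(D - 1L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default 5-part balance basis for the final-composition analysis
#'
#' Parts are ordered (A. aurita on panel, bare panel, Botrylloides spp.,
#' Bugula spp., M. tubifera). The sequential binary partition is
#' ((aurita, bare) vs competitors; aurita vs bare; Botrylloides vs
#' (Bugula, Molgula); Bugula vs Molgula), so the first two coordinates
#' carry the amalgamated (aurita, bare, competitors-as-a-whole) information
#' and the last two the within-competitor subcomposition: the two ternary
#' projections of the treatment-effect display are orthogonal coordinate
#' blocks.
#'
#' @return a `contrast_matrix` for D = 5.
#' @export
default_basis <- function() {
  sbp_basis(
    list(list(1:2, 3:5), list(1L, 2L), list(3L, 4:5), list(4L, 5L)),
    D = 5,
    labels = c("aurita+bare | competitors", "aurita | bare",
               "botrylloides | bugula+molgula", "bugula | molgula")
  )
}

#' Basis for a 3-part composition (single sequential partition)
#' @param first index pair grouping: defaults to ((1,2) vs 3; 1 vs 2).
#' @return a `contrast_matrix` for D = 3.
#' @export
ternary_basis <- function(first = list(list(1:2, 3L), list(1L, 2L))) {
  sbp_basis(first, D = 3)
}

#' Isometric logratio transform
#'
#' Maps a strictly positive composition (or matrix of compositions, one per
#' row) to its ilr coordinates, `V %*% log(x)` for a contrast matrix V whose
#' rows are orthonormal and sum to zero.
#'
#' @param x composition vector or matrix (rows).
#' @param basis a `contrast_matrix`; default [default_basis()] when D = 5.
#' @return numeric vector of length D-1, or matrix with D-1 columns.
#' @export
ilr <- function(x, basis = NULL) {
  if (is.matrix(x)) {
    basis <- basis %||% (if (ncol(x) == 5) default_basis() else stop("basis required"))
    if (ncol(x) != ncol(basis)) stop("basis dimension mismatch")
    if (any(x <= 0)) stop("ilr requires strictly positive parts (zero-replace first)")
    return(log(x) %*% t(unclass(basis)))
  }
  basis <- basis %||% (if (length(x) == 5) default_basis() else stop("basis required"))
  if (length(x) != ncol(basis)) stop("basis dimension mismatch")
  if (any(x <= 0)) stop("ilr requires strictly positive parts (zero-replace first)")
  drop(unclass(basis) %*% log(x))
}

#' Inverse isometric logratio transform
#'
#' @param z coordinate vector of length D-1, or matrix with D-1 columns.
#' @param basis a `contrast_matrix`.
#' @return closed composition (vector or matrix of rows).
#' @export
ilr_inv <- function(z, basis = NULL) {
  if (is.matrix(z)) {
    basis <- basis %||% (if (ncol(z) == 4) default_basis() else stop("basis required"))
    if (any(!is.finite(z))) stop("non-finite ilr coordinates")
    e <- exp(z %*% unclass(basis))
    return(e / rowSums(e))
  }
  basis <- basis %||% (if (length(z) == 4) default_basis() else stop("basis required"))
  if (any(!is.finite(z))) stop("non-finite ilr coordinates")
  close_comp(exp(drop(t(unclass(basis)) %*% z)))
}

#' Perturbation: the group operation of the simplex
#'
#' Closure of the elementwise product. Commutative; the uniform composition
#' is the neutral element; equals addition in ilr coordinates.
#'
#' @param a,b compositions of equal length.
#' @return closed composition.
#' @export
perturb <- function(a, b) {
  if (length(a) != length(b)) stop("compositions must have equal length")
  close_comp(a * b)
}

#' Subcomposition of selected parts
#'
#' Closure of the retained parts; ratios among retained parts are unchanged
#' (subcompositional coherence).
#'
#' @param x composition.
#' @param parts integer indices (at least two, in range).
#' @return closed composition over the retained parts.
#' @export
subcomposition <- function(x, parts) {
  if (length(parts) < 2L) stop("need at least two parts")
  if (any(parts < 1L) || any(parts > length(x))) stop("part index out of range")
  close_comp(x[parts])
}

#' Geometric-mean amalgamation to a 3-part composition
#'
#' Projects a 5-part composition (aurita, bare, competitor parts) to the
#' 3-part composition (aurita, bare, gm(competitors)), where gm is the
#' geometric mean of the competitor parts. Together with
#' [subcomposition()] over the competitor parts this realises the orthogonal
#' decomposition used for the two ternary displays of treatment effects.
#'
#' @param x 5-part composition.
#' @param group indices of the competitor parts (default 3:5).
#' @return 3-part closed composition.
#' @export
gm_amalgamate <- function(x, group = 3:5) {
  if (length(x) != 5L) stop("expected a 5-part composition")
  if (length(group) < 2L || any(group < 1L) || any(group > 5L))
    stop("invalid competitor group")
  rest <- setdiff(seq_along(x), group)
  g <- exp(mean(log(x[group])))
  close_comp(c(x[rest], g))
}

#' Aitchison distance between two compositions
#'
#' Euclidean distance between ilr images; independent of the orthonormal
#' basis chosen.
#' @param a,b compositions of equal length.
#' @param basis contrast matrix (any orthonormal one gives the same value).
#' @return nonnegative scalar.
#' @export
aitchison_dist <- function(a, b, basis = NULL) {
  basis <- basis %||% (if (length(a) == 5) default_basis() else
    sbp_basis(.default_partition(length(a)), length(a)))
  sqrt(sum((ilr(a, basis) - ilr(b, basis))^2))
}

# a generic sequential binary partition {1}|{2..D}, {2}|{3..D}, ...
.default_partition <- function(D) {
  lapply(seq_len(D - 1L), function(i) list(i, (i + 1L):D))
}

#' Ternary plot coordinates
#'
#' Maps 3-part compositions to 2-D coordinates of the equilateral triangle
#' with vertices part1 = (0,0), part2 = (1,0), part3 = (1/2, sqrt(3)/2).
#' @param p 3-part composition or matrix of rows.
#' @return matrix with columns x, y.
#' @export
ternary_xy <- function(p) {
  p <- if (is.matrix(p)) p else matrix(p, 1)
  cbind(x = p[, 2] + p[, 3] / 2, y = p[, 3] * sqrt(3) / 2)
}

#' @export
print.contrast_matrix <- function(x, ...) {
  cat("Orthonormal logratio contrast matrix (", nrow(x), "x", ncol(x), ")\n", sep = "")
  lb <- attr(x, "labels")
  M <- unclass(x)
  rownames(M) <- lb
  print(round(M, 4))
  invisible(x)
}

# serialize / read a basis as plain text
#' Write a contrast matrix (with partition labels) as plain text
#' @param basis a `contrast_matrix`.
#' @param path output file.
#' @export
write_basis <- function(basis, path) {
  M <- unclass(basis)
  df <- data.frame(label = attr(basis, "labels"), M, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
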