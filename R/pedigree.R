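#' Validate and normalise a pedigree
#'
#' Checks a 3-column pedigree (\code{animal, sire, dam}; \code{0}, \code{NA} or
#' \code{""} mark unknown parents), verifies that every named parent appears as
#' an animal, that no animal is its own ancestor, and reorders the rows so
#' parents precede offspring.
#'
#' @param ped Data frame with columns \code{animal, sire, dam}.
#' @return Tibble \code{animal, sire, dam} (original identifiers) sorted
#'   parents-first, with integer index columns \code{sire_i, dam_i} (0 =
#'   unknown) used internally.
#' @export
ped_normalise <- function(ped) {
  stopifnot_cols(ped, c("animal", "sire", "dam"), "`ped`")
  ped <- as_tibble(ped)
  an <- as.character(ped$animal)
  if (anyDuplicated(an)) abort("duplicate animal ids in pedigree.")
  clean <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x %in% c("0", "")] <- NA_character_
    x
  }
  si <- clean(ped$sire); da <- clean(ped$dam)
  unknown <- setdiff(c(si, da), c(an, NA_character_))
  if (length(unknown)) {
    abort(sprintf("parent(s) not listed as animals: %s",
                  paste(utils::head(unknown, 5), collapse = ", ")))
  }
  # topological sort (Kahn); cycle detection
  n <- length(an)
  idx <- setNames(seq_len(n), an)
  si_i <- ifelse(is.na(si), 0L, idx[si])
  da_i <- ifelse(is.na(da), 0L, idx[da])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si_i[i], da_i[i])) {
      if (p > 0L) { indeg[i] <- indeg[i] + 1L; children[[p]] <- c(children[[p]], i) }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) != n) {
    bad <- an[indeg > 0][1]
    abort(sprintf("pedigree contains a cycle involving animal '%s'.", bad))
  }
  out <- tibble(animal = an[ord], sire = si[ord], dam = da[ord])
  idx2 <- setNames(seq_len(n), out$animal)
  out$sire_i <- ifelse(is.na(out$sire), 0L, unname(idx2[out$sire]))
  out$dam_i <- ifelse(is.na(out$dam), 0L, unname(idx2[out$dam]))
  out
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes the pedigree inbreeding coefficient of every animal from the
#' \code{L D L'} decomposition of the numerator relationship matrix, tracing
#' each animal's ancestor contributions without forming the dense matrix.
#'
#' @param ped Pedigree as accepted by \code{\link{ped_normalise}}.
#' @return Named numeric vector of inbreeding coefficients, in the normalised
#'   (parents-first) order.
#' @export
inbreeding <- function(ped) {
  ped <- ped_normalise(ped)
  n <- nrow(ped)
  s <- ped$sire_i; d <- ped$dam_i
  Fc <- numeric(n)            # inbreeding coefficients
  Dv <- numeric(n)            # Mendelian sampling variances (diag of D)
  fpar <- function(j) if (j == 0L) -1 else Fc[j]   # unknown parent contributes F = -1
  for (i in seq_len(n)) {
    Dv[i] <- 0.5 - 0.25 * (fpar(s[i]) + fpar(d[i]))
    if (s[i] == 0L || d[i] == 0L) { Fc[i] <- 0; next }
    # a_ii = sum_j L_ij^2 D_j via backward traversal from i
    L <- numeric(i); L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * Dv[j]
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * L[j]
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * L[j]
    }
    Fc[i] <- aii - 1
  }
  setNames(Fc, ped$animal)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles \eqn{A^{-1}} directly by Henderson's rules, with
#' Mendelian-sampling variances adjusted for inbreeding (inbreeding
#' coefficients from \code{\link{inbreeding}}). For each animal with
#' Mendelian-sampling variance \eqn{d_i}, \eqn{1/d_i} is added at the animal's
#' diagonal, \eqn{-1/(2 d_i)} between animal and each known parent, and
#' \eqn{1/(4 d_i)} among the known parents.
#'
#' @param ped Pedigree as accepted by \code{\link{ped_normalise}}.
#' @return Sparse symmetric matrix (class \code{dsCMatrix}) in parents-first
#'   order, with dimnames the animal ids and attributes \code{"logdet_A"}
#'   (log-determinant of \eqn{A}) and \code{"F"} (inbreeding coefficients).
#' @export
a_inverse <- function(ped) {
  ped <- ped_normalise(ped)
  n <- nrow(ped)
  Fc <- inbreeding(ped)
  s <- ped$sire_i; d <- ped$dam_i
  fpar <- ifelse(s == 0L, -1, Fc[pmax(s, 1L)])
  fmar <- ifelse(d == 0L, -1, Fc[pmax(d, 1L)])
  Dv <- 0.5 - 0.25 * (fpar + fmar)
  alpha <- 1 / Dv
  ii <- list(); jj <- list(); xx <- list()
  add <- function(i, j, v) {
    k <- length(ii) + 1L
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- v
  }
  an <- seq_len(n)
  add(an, an, alpha)
  hs <- s > 0L; hd <- d > 0L
  add(an[hs], s[hs], -alpha[hs] / 2)
  add(an[hd], d[hd], -alpha[hd] / 2)
  add(s[hs], s[hs], alpha[hs] / 4)
  add(d[hd], d[hd], alpha[hd] / 4)
  both <- hs & hd
  add(s[both], d[both], alpha[both] / 4)
  i <- unlist(ii); j <- unlist(jj); x <- unlist(xx)
  # store lower triangle, symmetric
  lo <- pmax(i, j); hi <- pmin(i, j)
  Ainv <- Matrix::sparseMatrix(i = lo, j = hi, x = x, dims = c(n, n),
                               symmetric = TRUE,
                               dimnames = list(ped$animal, ped$animal))
  attr(Ainv, "logdet_A") <- sum(log(Dv))
  attr(Ainv, "F") <- Fc
  Ainv
}
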