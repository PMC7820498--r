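#' @importFrom rlang %||% .data abort warn
#' @importFrom stats var sd setNames model.matrix rnorm runif optimize pchisq pt qt
#' @importFrom dplyr mutate filter select group_by ungroup summarise arrange left_join
#'   bind_rows n row_number across all_of
#' @importFrom tibble tibble as_tibble
NULL

# half-vectorisation index pairs (i >= j, column order) for a k x k symmetric matrix
vech_pairs <- function(k) {
  idx <- which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
}

vech <- function(M) M[lower.tri(M, diag = TRUE)]

unvech <- function(v, k) {
  M <- matrix(0, k, k)
  M[lower.tri(M, diag = TRUE)] <- v
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  M
}

is_psd <- function(M, tol = -1e-10) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  all(ev >= tol * max(1, abs(ev[1])))
}

sig_stars <- function(p) ifelse(!is.na(p) & p < 0.01, "*", "")

stopifnot_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("%s is missing required column(s): %s", what,
                  paste(miss, collapse = ", ")))
  }
  invisible(df)
}
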