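# Public mask-attention primitives. Feature maps may be given either as
# h x w x c arrays or as (positions x channels) matrices; results follow the
# input layout.

as_feature_matrix <- function(map) {
  if (is.matrix(map)) return(list(m = map, dim = NULL))
  d <- dim(map)
  if (is.null(d) || length(d) != 3)
    err_shape("feature map must be an h x w x c array or positions x channels matrix")
  list(m = matrix(map, d[1] * d[2], d[3]), dim = d)
}

#' Pointwise (1x1) feature projection
#'
#' Applies a per-position linear map of the channel vector, the 1x1
#' convolution that produces the attention query/key feature maps from the
#' encoder streams. Spatial shape is preserved.
#'
#' @param map Feature map, `h x w x c` array or `positions x channels` matrix.
#' @param weights `in_channels x out_channels` matrix.
#' @return Projected feature map in the same layout as `map`.
#' @export
project_features <- function(map, weights) {
  fm <- as_feature_matrix(map)
  if (ncol(fm$m) != nrow(weights))
    err_shape(sprintf("map has %d channels but weights expect %d",
                      ncol(fm$m), nrow(weights)))
  out <- fm$m %*% weights
  if (!is.null(fm$dim)) out <- array(out, c(fm$dim[1], fm$dim[2], ncol(weights)))
  out
}

#' Position-wise similarity of two feature maps
#'
#' `S[i, j]` is the inner product of the channel vector of `A` at flattened
#' position `i` with that of `B` at position `j` — the matrix-multiplication
#' coupling of the two encoder streams.
#'
#' @param A,B Feature maps sharing spatial shape and channel count.
#' @return An `N x N` similarity matrix, `N` = number of spatial positions.
#' @export
similarity <- function(A, B) {
  fa <- as_feature_matrix(A)
  fb <- as_feature_matrix(B)
  if (!identical(dim(fa$m), dim(fb$m)))
    err_shape("A and B must share spatial shape and channel count")
  tcrossprod(fa$m, fb$m)
}

#' Column-softmax attention distribution
#'
#' Normalizes each column of the similarity matrix with a numerically
#' stabilized softmax over positions `i`, so every column `j` is a probability
#' distribution of attention over source positions.
#'
#' @param S Finite similarity matrix.
#' @return Column-stochastic matrix of the same shape; attribute
#'   `position_count` records `N`.
#' @export
attention_distribution <- function(S) {
  if (!is.matrix(S) || !all(is.finite(S)))
    err_shape("S must be a finite numeric matrix")
  D <- softmax_cols(S)
  attr(D, "position_count") <- nrow(S)
  D
}

#' Aggregate a feature map under an attention distribution
#'
#' Output position `j` is the attention-weighted sum over source positions
#' `i` of the channel vectors of `V`. The caller adds the result to the
#' decoder stream through a residual connection.
#'
#' @param D Attention distribution from [attention_distribution()].
#' @param V Feature map whose position count equals `nrow(D)`.
#' @return Aggregated feature map in `V`'s layout.
#' @export
apply_attention <- function(D, V) {
  fv <- as_feature_matrix(V)
  if (nrow(fv$m) != nrow(D))
    err_shape(sprintf("V has %d positions but D expects %d",
                      nrow(fv$m), nrow(D)))
  out <- crossprod(D, fv$m)
  if (!is.null(fv$dim)) out <- array(out, fv$dim)
  out
}
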