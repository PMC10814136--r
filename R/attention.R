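#' Sinusoidal positional encoding
#'
#' The fixed position code added to token embeddings in a Transformer
#' encoder: `PE[pos, 2i] = sin(pos / 10000^(2i/d_model))` and
#' `PE[pos, 2i+1] = cos(pos / 10000^(2i/d_model))`, with `pos` starting
#' at 0. For spectra each band is one sequence position, so the encoding
#' carries relative wavelength-order information into the attention layers.
#'
#' @param seq_len number of positions (bands), `>= 1`.
#' @param d_model embedding width, even, `>= 1`.
#' @return `seq_len x d_model` matrix with entries in `[-1, 1]`.
#' @export
positional_encoding <- function(seq_len, d_model) {
  if (seq_len < 1 || d_model < 1)
    stop("positional_encoding: dimensions must be >= 1")
  if (d_model %% 2 != 0)
    stop("positional_encoding: `d_model` must be even")
  pos <- 0:(seq_len - 1)
  i <- 0:(d_model / 2 - 1)
  ang <- outer(pos, 10000^(2 * i / d_model), "/")
  pe <- matrix(0, seq_len, d_model)
  pe[, 2 * i + 1] <- sin(ang)
  pe[, 2 * i + 2] <- cos(ang)
  pe
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V` with the softmax taken along each row of
#' the score matrix, the core operator of Multi-Head Attention.
#'
#' @param Q query matrix, `n x d_k`.
#' @param K key matrix, `m x d_k`.
#' @param V value matrix, `m x d_v`.
#' @return `n x d_v` output matrix; attribute `"weights"` carries the
#'   `n x m` attention weight matrix (rows sum to 1).
#' @export
scaled_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K))
    stop("scaled_attention: Q and K widths differ")
  if (nrow(K) != nrow(V))
    stop("scaled_attention: K and V row counts differ")
  s <- Q %*% t(K) / sqrt(ncol(K))
  # subtract row max before exponentiating for numerical stability
  s <- s - apply(s, 1, max)
  w <- exp(s)
  w <- w / rowSums(w)
  out <- w %*% V
  attr(out, "weights") <- w
  out
}
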