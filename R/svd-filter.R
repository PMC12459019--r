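#' SVD clutter filtering of a volume batch
#'
#' Rejects static and slowly varying tissue signal by zeroing the largest
#' singular values of the spatiotemporal (Casorati) matrix — voxels as
#' rows, time as columns — of a batch of volumes. The discard count is
#' `k = round(discard_fraction * n_frames)`; the magnitude of the
#' reconstruction is returned so intensities stay nonnegative.
#'
#' The decomposition is computed through the eigendecomposition of the
#' small time-by-time Gram matrix, which is exactly equivalent to a full
#' singular value decomposition of the Casorati matrix for the purpose of
#' removing the top-k subspace.
#'
#' @param batch 4-D array or [volume_stack()] slice of one batch.
#' @param discard_fraction Fraction of singular values discarded
#'   (default 0.10; the regime used in practice is 0.10-0.15).
#' @param k Optional explicit discard count overriding `discard_fraction`.
#' @return The filtered batch, same shape and class as the input.
#' @examples
#' x <- array(abs(rnorm(8 * 8 * 8 * 10)), c(8, 8, 8, 10))
#' f <- svd_filter_batch(x, discard_fraction = 0.1)
#' @export
svd_filter_batch <- function(batch, discard_fraction = 0.10, k = NULL) {
  arr <- if (inherits(batch, "volume_stack")) batch$data else batch
  stopifnot(is.array(arr), length(dim(arr)) == 4)
  d <- dim(arr)
  nt <- d[4]
  if (is.null(k)) k <- round(discard_fraction * nt)
  k <- as.integer(k)
  stopifnot(k >= 0, k < nt)
  X <- matrix(arr, nrow = prod(d[1:3]), ncol = nt)
  if (all(X == 0)) {
    warning("svd_filter_batch: batch is identically zero")
    return(batch)
  }
  if (k > 0) {
    G <- crossprod(X)                      # nt x nt
    eig <- eigen(G, symmetric = TRUE)      # eigenvalues descending
    Vk <- eig$vectors[, seq_len(k), drop = FALSE]
    X <- X - (X %*% Vk) %*% t(Vk)
  }
  out <- array(abs(X), d)
  if (inherits(batch, "volume_stack")) {
    batch$data <- out
    batch
  } else {
    out
  }
}

#' Batchwise SVD clutter filtering of a full stack
#'
#' Splits the stack into consecutive batches of `batch_size` volumes
#' (default 200, i.e. 0.4 s at 500 vps) and filters each independently
#' with [svd_filter_batch()]. A trailing partial batch is processed with
#' a proportionally scaled discard count (at least one component),
#' reported via a message.
#'
#' @param stack A [volume_stack()].
#' @param batch_size Volumes per batch.
#' @param discard_fraction Fraction of singular values discarded per batch.
#' @param verbose Emit a message per batch with the discard count.
#' @return The filtered [volume_stack()].
#' @export
svd_filter <- function(stack, batch_size = 200, discard_fraction = 0.10,
                       verbose = FALSE) {
  stopifnot(inherits(stack, "volume_stack"), batch_size >= 2)
  k_full <- round(discard_fraction * batch_size)
  stopifnot(k_full >= 1, k_full < batch_size)
  nt <- n_volumes(stack)
  starts <- seq(1L, nt, by = batch_size)
  for (s in starts) {
    e <- min(s + batch_size - 1L, nt)
    nb <- e - s + 1L
    k <- max(1L, round(discard_fraction * nb))
    if (nb < batch_size) {
      message("svd_filter: trailing batch of ", nb,
              " volumes, discarding k = ", k)
    }
    if (k >= nb) {
      warning("svd_filter: skipping batch shorter than its discard count")
      next
    }
    if (verbose) message("svd_filter: frames ", s, "-", e, ", k = ", k)
    stack$data[, , , s:e] <- svd_filter_batch(
      stack$data[, , , s:e, drop = FALSE], k = k)
  }
  stack
}
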