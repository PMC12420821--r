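#' Time-invariant spike-time separation loss
#'
#' Mean-squared-error loss on spike-time differences,
#' \deqn{L = \frac{1}{2}\sum_{n \ne n^\star}
#'   \left[(t_n - t_{n^\star}) - \Delta_t\right]^2,}
#' which penalizes every wrong-label output neuron for not firing exactly
#' \eqn{\Delta_t} after the correct-label neuron. Because only differences
#' enter, the loss is invariant under a uniform shift of all output times.
#' Averaged over the batch.
#'
#' Silent handling: a silent wrong-label neuron contributes nothing (it
#' already fires "infinitely late"); when the correct-label neuron is
#' silent its time is replaced by a proxy (the sample's latest finite
#' output plus \eqn{\Delta_t}), which pushes the wrong neurons later while
#' the silent-neuron weight bump (see [train_network()]) revives the
#' correct one. All-silent samples contribute zero loss and gradient.
#'
#' @param output_times `B x n_out` matrix (or length-`n_out` vector) of
#'   output spike times.
#' @param correct_index Integer vector (length `B`) of correct-label neuron
#'   indices.
#' @param delta_t Target separation (time units); must be positive.
#' @return Scalar loss (mean over the batch).
#' @export
loss_delta_mse <- function(output_times, correct_index, delta_t = 0.2) {
  loss_delta_mse_grad(output_times, correct_index, delta_t)$loss
}

#' Loss and gradient of the spike-time separation loss
#'
#' @inheritParams loss_delta_mse
#' @return A list with `loss` (scalar) and `grad` (`B x n_out` matrix of
#'   \eqn{\partial L/\partial t}, already divided by the batch size).
#' @export
loss_delta_mse_grad <- function(output_times, correct_index, delta_t = 0.2) {
  stopifnot(delta_t > 0)
  Tm <- if (is.matrix(output_times)) output_times else
    matrix(output_times, nrow = 1L)
  B <- nrow(Tm); P <- ncol(Tm)
  lab <- cbind(seq_len(B), correct_index)
  tstar <- Tm[lab]
  # proxy for silent correct neurons: latest finite output + delta_t
  fin <- is.finite(Tm)
  rowmax <- apply(ifelse(fin, Tm, -Inf), 1L, max)
  tstar <- ifelse(is.finite(tstar), tstar, rowmax + delta_t)
  diffm <- Tm - tstar - delta_t
  wrong <- matrix(TRUE, B, P); wrong[lab] <- FALSE
  act <- wrong & fin & is.finite(tstar)
  diffm[!act] <- 0
  loss <- sum(0.5 * diffm^2) / B
  grad <- diffm / B
  # correct neuron collects the negated sum (only where it actually fired)
  gstar <- -rowSums(diffm) / B
  gstar[!is.finite(Tm[lab])] <- 0
  grad[lab] <- gstar
  list(loss = loss, grad = grad)
}

#' Time-to-first-spike readout
#'
#' The earliest-firing output neuron determines the predicted class; ties
#' resolve to the lowest index (deterministic). A sample whose output
#' neurons are all silent has no prediction (`NA`), scored as an error.
#'
#' @param output_times `B x n_out` matrix or length-`n_out` vector.
#' @return Integer vector of predicted class indices (`NA` if all silent).
#' @export
predict_ttfs <- function(output_times) {
  Tm <- if (is.matrix(output_times)) output_times else
    matrix(output_times, nrow = 1L)
  idx <- max.col(-Tm, ties.method = "first")
  idx[!is.finite(Tm[cbind(seq_len(nrow(Tm)), idx)])] <- NA_integer_
  idx
}

#' Test error of a model on a dataset
#'
#' Percentage of samples whose TTFS prediction differs from the label;
#' samples with no prediction (all output neurons silent) count as errors.
#'
#' @param model An `snn_model`.
#' @param dataset A list with `times` (`n x 4` input spike matrix) and
#'   `labels` (integer classes), as from [yinyang_dataset()].
#' @return Test error in percent.
#' @export
evaluate_network <- function(model, dataset) {
  out <- network_forward(dataset$times, model)$output
  pred <- predict_ttfs(out)
  100 * mean(is.na(pred) | pred != dataset$labels)
}
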