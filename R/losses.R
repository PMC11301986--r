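# Loss primitives: focal loss, homoscedastic multi-task combination,
# top-one (softmax) probabilities and the listwise KL ranking loss.

FOCAL_EPS <- 1e-7

#' Focal loss
#'
#' Binary cross-entropy modulated by `(1-p)^gamma` (positives) or `p^gamma`
#' (negatives), down-weighting easy examples; reduces to plain binary
#' cross-entropy at `gamma = 0`. Probabilities are clamped to
#' `[1e-7, 1 - 1e-7]` before taking logs.
#'
#' @param p predicted probabilities in `[0,1]` (vector or matrix).
#' @param y binary indicators, same shape as `p`.
#' @param gamma modulating factor, `>= 0`.
#' @return element-wise non-negative losses, same shape as `p`.
#' @export
#' @examples
#' focal_loss(0.5, 1, gamma = 0)   # -log(0.5)
#' focal_loss(0.9, 0, gamma = 2)   # 0.81 * log(10)
focal_loss <- function(p, y, gamma = 2) {
  if (length(gamma) != 1 || is.na(gamma) || gamma < 0) {
    stop("gamma must be a single non-negative number", call. = FALSE)
  }
  pc <- clamp(p, FOCAL_EPS, 1 - FOCAL_EPS)
  pos <- -(1 - pc)^gamma * log(pc)
  neg <- -pc^gamma * log(1 - pc)
  out <- ifelse(y == 1, pos, neg)
  if (is.matrix(p)) dim(out) <- dim(p)
  out
}

# d focal / d p, element-wise (same clamping convention as focal_loss).
focal_loss_grad <- function(p, y, gamma) {
  pc <- clamp(p, FOCAL_EPS, 1 - FOCAL_EPS)
  if (gamma == 0) {
    gpos <- -1 / pc
    gneg <- 1 / (1 - pc)
  } else {
    gpos <- gamma * (1 - pc)^(gamma - 1) * log(pc) - (1 - pc)^gamma / pc
    gneg <- -gamma * pc^(gamma - 1) * log(1 - pc) + pc^gamma / (1 - pc)
  }
  out <- ifelse(y == 1, gpos, gneg)
  if (is.matrix(p)) dim(out) <- dim(p)
  out
}

#' Homoscedastic multi-task loss combination
#'
#' Combines two task losses with learned uncertainty weights:
#' `L = L_r/(2*sigma_r) + L_s/(2*sigma_s) + log(sigma_r * sigma_s)`.
#' A `variant = "sigma2"` switch uses the `1/(2*sigma^2)` weighting of the
#' homoscedastic-uncertainty literature instead.
#'
#' @param loss_r,loss_s finite task losses.
#' @param sigma_r,sigma_s positive uncertainty parameters.
#' @param variant `"sigma"` (default) or `"sigma2"`.
#' @return the combined scalar loss.
#' @export
#' @examples
#' combined_multitask_loss(1, 1, 0.5, 0.5)  # 2 + log(0.25)
combined_multitask_loss <- function(loss_r, loss_s, sigma_r, sigma_s,
                                    variant = c("sigma", "sigma2")) {
  variant <- match.arg(variant)
  if (!is.finite(loss_r) || !is.finite(loss_s)) {
    stop("non-finite task loss", call. = FALSE)
  }
  if (sigma_r <= 0 || sigma_s <= 0) {
    stop("sigma parameters must be positive", call. = FALSE)
  }
  if (variant == "sigma") {
    loss_r / (2 * sigma_r) + loss_s / (2 * sigma_s) + log(sigma_r * sigma_s)
  } else {
    loss_r / (2 * sigma_r^2) + loss_s / (2 * sigma_s^2) +
      log(sigma_r * sigma_s)
  }
}

# Task weight and d(combined)/d(log sigma) for the chosen variant, used
# during training where sigma is parameterized by its logarithm.
multitask_weight <- function(sigma, variant) {
  if (variant == "sigma") 1 / (2 * sigma) else 1 / (2 * sigma^2)
}
multitask_logsigma_grad <- function(task_loss, sigma, variant) {
  if (variant == "sigma") -task_loss / (2 * sigma) + 1
  else -task_loss / sigma^2 + 1
}

#' Top-one probability of a score list
#'
#' Softmax over a list's scores: the ListNet probability that each item ranks
#' first. Computed with max-subtraction, so it is shift-invariant and stable.
#'
#' @param scores finite numeric vector, length >= 1.
#' @return probability vector summing to 1.
#' @export
top_one_probability <- function(scores) {
  if (length(scores) == 0) stop("empty score list", call. = FALSE)
  if (any(!is.finite(scores))) stop("non-finite scores", call. = FALSE)
  e <- exp(scores - max(scores))
  e / sum(e)
}

#' Listwise KL ranking loss
#'
#' Kullback-Leibler divergence `KL(P_target || P_predicted)` between the
#' top-one probability distributions induced by the target relevance scores
#' and the predicted scores. Zero exactly when the two distributions coincide.
#'
#' @param predicted predicted scores.
#' @param target target relevance scores (same length).
#' @return non-negative scalar.
#' @export
listwise_kl_loss <- function(predicted, target) {
  if (length(predicted) != length(target)) {
    stop("predicted and target lengths differ", call. = FALSE)
  }
  pt <- top_one_probability(target)
  pp <- top_one_probability(predicted)
  nz <- pt > 0
  sum(pt[nz] * (log(pt[nz]) - log(pp[nz])))
}

sigmoid <- function(x) 1 / (1 + exp(-clamp(x, -35, 35)))
relu <- function(x) {
  x[x < 0] <- 0
  x
}
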