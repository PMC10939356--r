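# Generator loss suite: colour (cycle + identity), shape (cross-cycle
# MS-SSIM), adversarial (least squares) and the entropy-weighted total.

mean_l1 <- function(a, b) {
  if (!all(dim(a)[1:2] == dim(b)[1:2])) stop("dimension mismatch")
  mean(abs(as_rgb01(a) - as_rgb01(b)))
}

as_rgb01 <- function(x) {
  if (length(dim(x)) == 3L && dim(x)[3] == 4L) composite_white(x) else x
}

#' Cycle-consistency loss
#'
#' `mean-L1(s, G_TS(G_ST(s))) + mean-L1(t, G_ST(G_TS(t)))`: translating to
#' the other domain and back must reproduce the input.
#'
#' @param s,t real source / target images (RGB or RGBA; RGBA is composited
#'   over white).
#' @param rec_s,rec_t their reconstructions through both generators.
#' @return scalar `>= 0`.
#' @export
cycle_loss <- function(s, rec_s, t, rec_t) mean_l1(s, rec_s) + mean_l1(t, rec_t)

#' Identity loss
#'
#' A generator fed an image of its own output domain should leave it
#' unchanged: `mean-L1(t, G_ST(t)) + mean-L1(s, G_TS(s))`.
#'
#' @param s,t real source / target images.
#' @param id_s,id_t the identity-mapped images.
#' @return scalar `>= 0`.
#' @export
identity_loss <- function(s, id_s, t, id_t) mean_l1(s, id_s) + mean_l1(t, id_t)

#' Colour loss
#'
#' Combines the cycle-consistency and identity components,
#' `lambda_cycle * L_cycle + lambda_identity * L_identity`. The relative
#' ratio 10:5 stabilizes training (unit weights make the identity term too
#' weak to anchor colours); the entropy weight `W_c` is applied outside, in
#' [total_loss()].
#'
#' @param cycle,identity non-negative loss components.
#' @param ratios named vector `c(cycle = , identity = )`.
#' @return scalar `>= 0`.
#' @export
color_loss <- function(cycle, identity, ratios = c(cycle = 10, identity = 5)) {
  if (cycle < 0 || identity < 0) stop("loss components must be non-negative")
  ratios[["cycle"]] * cycle + ratios[["identity"]] * identity
}

#' Cross-cycle shape loss
#'
#' `(1 - MS_SSIM(G_ST(s), t)) + (1 - MS_SSIM(G_TS(t), s))`: each generated
#' image is compared with the real (unpaired) sample from the opposite
#' cycle of the same mini-batch, so the generator is pushed towards the
#' target domain's geometry rather than its own reconstruction.
#'
#' @param gen_st,real_t,gen_ts,real_s images of identical size.
#' @param cfg an [msssim_config()].
#' @return scalar in `[0, 4)`.
#' @export
shape_loss <- function(gen_st, real_t, gen_ts, real_s, cfg = msssim_config()) {
  (1 - ms_ssim(gen_st, real_t, cfg)) + (1 - ms_ssim(gen_ts, real_s, cfg))
}

#' Least-squares adversarial losses
#'
#' Patch-discriminator objectives in both domains. Each discriminator
#' minimizes `mean((D(real) - 1)^2) + mean(D(fake)^2)`; the generators
#' minimize `mean((D(fake) - 1)^2)`, averaged over the two domains.
#'
#' @param d_real_t,d_fake_t discriminator output patches in the target
#'   domain for a real and a generated image.
#' @param d_real_s,d_fake_s the same in the source domain.
#' @return list with `L_adv_G`, `L_adv_D_A` (target-domain discriminator,
#'   Domain Cycle A) and `L_adv_D_B` (source-domain discriminator).
#' @export
adversarial_losses <- function(d_real_t, d_fake_t, d_real_s, d_fake_s) {
  list(L_adv_G = 0.5 * (mean((d_fake_t - 1)^2) + mean((d_fake_s - 1)^2)),
       L_adv_D_A = mean((d_real_t - 1)^2) + mean(d_fake_t^2),
       L_adv_D_B = mean((d_real_s - 1)^2) + mean(d_fake_s^2))
}

#' Total generator objective
#'
#' `L_adv_G + W_s * L_shape + W_c * L_color + W_t * L_texture`, with the
#' entropy weights summing to one over the three phenotype losses. The
#' adversarial term enters unweighted (set `adv_g = 0` to recover the purely
#' phenotype-weighted sum).
#'
#' @param adv_g adversarial generator loss.
#' @param shape,color,texture phenotype loss components.
#' @param weights a [loss_weights()] triple `(W_s, W_c, W_t)`.
#' @return scalar total loss.
#' @export
total_loss <- function(adv_g, shape, color, texture, weights) {
  w <- as.numeric(weights)
  if (abs(sum(w) - 1) > 1e-6) stop("loss weights must sum to 1")
  adv_g + w[1] * shape + w[2] * color + w[3] * texture
}
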