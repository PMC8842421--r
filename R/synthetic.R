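#' Synthetic observer-study configuration
#'
#' Parameters of the seeded generator that emulates a two-condition
#' (color/grayscale) translucency study: a latent translucency continuum
#' over images, observers who judge a noisy percept of it against their own
#' criterion, attribute ratings driven by the same percept (see-throughness,
#' glow, glossiness) or by an independent anti-correlated softness/density
#' latent, and material categorization with condition-dependent confusion.
#' Removing color is modeled as both signal attenuation (`alpha_gray`) and
#' noise inflation (`beta_gray`), because label flips and extra disagreement
#' require both mechanisms. Defaults are calibrated to reproduce the
#' qualitative structure such studies report, not fitted to any data set.
#'
#' @param n_images number of images (default 300).
#' @param n_observers_binary observers per condition for classification and
#'   rating (default 20).
#' @param n_observers_category observers per condition who also categorize
#'   (default 15, a subset of the binary observers).
#' @param signal scale mapping the centered latent translucency score
#'   `t_i - 1/2` to the percept (default 3).
#' @param sigma_noise percept noise SD in the color condition (default 1).
#' @param sigma_criterion SD of observers' decision criteria (default 0.3).
#' @param alpha_gray signal attenuation in grayscale, in (0, 1\] (default
#'   0.7).
#' @param beta_gray noise inflation in grayscale, >= 1 (default 1.5).
#' @param shift_gray additive latent shift applied to glossiness, glow,
#'   softness and density in grayscale (default -0.3), producing the
#'   downward rating shifts color removal induces.
#' @param rating_loadings named vector: weight of the shared percept in the
#'   see-throughness, glow and glossiness rating latents.
#' @param rating_noise named vector of rating-latent noise SDs.
#' @param softdense_loading weight of the independent material latent in the
#'   (anti-correlated) softness and density latents (default 1).
#' @param thresholds 5 ordinal cut points for 6-point discretization,
#'   symmetric about 0 by default.
#' @param p_correct named vector: probability a categorization trial picks
#'   the ground-truth fine category, per condition.
#' @param p_crossfood named vector: probability an error crosses the
#'   food/non-food boundary, per condition (larger in grayscale).
#' @param food_slope,food_base ground-truth food probability is
#'   `food_base + food_slope * t_i`, concentrating food at translucent
#'   images.
#' @param seed generator seed.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_images = 300,
                             n_observers_binary = 20,
                             n_observers_category = 15,
                             signal = 3,
                             sigma_noise = 1,
                             sigma_criterion = 0.3,
                             alpha_gray = 0.7,
                             beta_gray = 1.5,
                             shift_gray = -0.3,
                             rating_loadings = c(see_throughness = 0.8,
                                                 glow = 0.7,
                                                 glossiness = 0.5),
                             rating_noise = c(see_throughness = 0.5,
                                              glow = 0.8,
                                              glossiness = 0.9,
                                              softness = 0.6,
                                              density = 0.6),
                             softdense_loading = 1,
                             thresholds = c(-1.5, -0.75, 0, 0.75, 1.5),
                             p_correct = c(color = 0.8, grayscale = 0.65),
                             p_crossfood = c(color = 0.3, grayscale = 0.55),
                             food_slope = 0.5,
                             food_base = 0.2,
                             seed = 1) {
  cfg <- list(n_images = n_images,
              n_observers_binary = n_observers_binary,
              n_observers_category = n_observers_category,
              signal = signal, sigma_noise = sigma_noise,
              sigma_criterion = sigma_criterion,
              alpha_gray = alpha_gray, beta_gray = beta_gray,
              shift_gray = shift_gray,
              rating_loadings = rating_loadings,
              rating_noise = rating_noise,
              softdense_loading = softdense_loading,
              thresholds = thresholds,
              p_correct = p_correct, p_crossfood = p_crossfood,
              food_slope = food_slope, food_base = food_base,
              seed = seed)
  problems <- character(0)
  if (n_images < 1) problems <- c(problems, "n_images must be >= 1")
  if (n_observers_category > n_observers_binary) {
    problems <- c(problems,
                  "n_observers_category must not exceed n_observers_binary")
  }
  if (alpha_gray <= 0 || alpha_gray > 1) {
    problems <- c(problems, "alpha_gray must lie in (0, 1]")
  }
  if (beta_gray < 1) problems <- c(problems, "beta_gray must be >= 1")
  if (any(p_correct < 0 | p_correct > 1)) {
    problems <- c(problems, "p_correct must lie in [0, 1]")
  }
  if (any(p_crossfood < 0 | p_crossfood > 1)) {
    problems <- c(problems, "p_crossfood must lie in [0, 1]")
  }
  if (is.unsorted(thresholds, strictly = TRUE) || length(thresholds) != 5) {
    problems <- c(problems, "thresholds must be 5 strictly increasing values")
  }
  mx <- food_base + food_slope
  if (food_base < 0 || mx > 1) {
    problems <- c(problems, "food probability must stay in [0, 1]")
  }
  if (length(problems) > 0) {
    stop("invalid synthetic config: ", paste(problems, collapse = "; "))
  }
  structure(cfg, class = "synthetic_config")
}

discretize6 <- function(latent, thresholds) {
  1L + rowSums(outer(latent, thresholds, `>`))
}

FOOD_FINE <- c("food in general", "food/cheese", "food/fruit/vegetables",
               "food/gummi/jelly", "food/meat/seafood", "food/candy/sugar",
               "food/shaved ice/ice cream/cream")
NONFOOD_FINE <- c("crystal/quartz/mineral/jade", "glass", "ivory",
                  "marble/stone/concrete", "plastic/synthetic", "rubber",
                  "soap", "wax", "metal")

generate_condition <- function(cfg, condition, t, m, prefix) {
  alpha <- if (condition == "grayscale") cfg$alpha_gray else 1
  beta <- if (condition == "grayscale") cfg$beta_gray else 1
  shift <- if (condition == "grayscale") cfg$shift_gray else 0
  n_i <- cfg$n_images
  n_o <- cfg$n_observers_binary
  obs <- sprintf("%s%02d", prefix, seq_len(n_o))
  imgs <- sprintf("img%03d", seq_len(n_i))
  crit <- rnorm(n_o, 0, cfg$sigma_criterion)
  signal_part <- alpha * cfg$signal * (t - 0.5)

  # shared percept drives both the binary label and the transmission-related
  # rating latents, so an observer's ratings predict their own labels
  percept <- matrix(signal_part, n_i, n_o) +
    matrix(rnorm(n_i * n_o, 0, cfg$sigma_noise * beta), n_i, n_o)
  binary <- (percept > matrix(crit, n_i, n_o, byrow = TRUE)) * 1L
  dimnames(binary) <- list(imgs, obs)

  lat <- list(
    see_throughness = cfg$rating_loadings["see_throughness"] * percept +
      rnorm(n_i * n_o, 0, cfg$rating_noise["see_throughness"]),
    glow = cfg$rating_loadings["glow"] * percept + shift +
      rnorm(n_i * n_o, 0, cfg$rating_noise["glow"]),
    glossiness = cfg$rating_loadings["glossiness"] * percept + shift +
      rnorm(n_i * n_o, 0, cfg$rating_noise["glossiness"]),
    softness = cfg$softdense_loading * matrix(m, n_i, n_o) + shift +
      rnorm(n_i * n_o, 0, cfg$rating_noise["softness"]),
    density = -cfg$softdense_loading * matrix(m, n_i, n_o) + shift +
      rnorm(n_i * n_o, 0, cfg$rating_noise["density"]))
  ratings <- expand.grid(image_id = imgs, observer_id = obs,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (a in TLC_ATTRIBUTES) {
    ratings[[a]] <- discretize6(as.vector(lat[[a]]), cfg$thresholds)
  }
  ratings <- ratings[, c("observer_id", "image_id", TLC_ATTRIBUTES)]
  list(binary = binary, ratings = ratings, observers = obs, images = imgs)
}

generate_categories <- function(cfg, condition, ground_truth, observers,
                                images) {
  pc <- cfg$p_correct[[condition]]
  px <- cfg$p_crossfood[[condition]]
  n_o <- cfg$n_observers_category
  obs <- observers[seq_len(n_o)]
  grid <- expand.grid(image_id = images, observer_id = obs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth <- ground_truth[grid$image_id]
  truth_is_food <- truth %in% FOOD_FINE
  n <- nrow(grid)
  correct <- runif(n) < pc
  cross <- runif(n) < px
  pick <- function(pool) pool[sample.int(length(pool), 1)]
  choice <- character(n)
  choice[correct] <- truth[correct]
  for (idx in which(!correct)) {
    same_side <- if (truth_is_food[idx]) FOOD_FINE else NONFOOD_FINE
    other_side <- if (truth_is_food[idx]) NONFOOD_FINE else FOOD_FINE
    pool <- if (cross[idx]) other_side else setdiff(same_side, truth[idx])
    choice[idx] <- pick(pool)
  }
  data.frame(observer_id = grid$observer_id, image_id = grid$image_id,
             category = choice, stringsAsFactors = FALSE)
}

#' Generate a color/grayscale panel pair
#'
#' Draws a full synthetic study from a [synthetic_config()]: binary
#' classifications, attribute ratings and material categorizations for two
#' independent observer groups viewing the same images in color and in
#' grayscale. All randomness comes from `config$seed`, so equal configs give
#' identical panels.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `color` and `grayscale` (each a
#'   [response_panel()]) and `latent` (data frame of per-image latent
#'   translucency `t` and material latent `m`).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  t <- runif(config$n_images)
  m <- rnorm(config$n_images)
  imgs <- sprintf("img%03d", seq_len(config$n_images))

  # ground-truth categories: food concentrated at mid-to-high translucency
  is_food <- runif(config$n_images) <
    config$food_base + config$food_slope * t
  gt <- ifelse(is_food,
               FOOD_FINE[sample.int(length(FOOD_FINE), config$n_images,
                                    replace = TRUE)],
               NONFOOD_FINE[sample.int(length(NONFOOD_FINE), config$n_images,
                                       replace = TRUE)])
  names(gt) <- imgs

  cc <- generate_condition(config, "color", t, m, "c")
  gc_ <- generate_condition(config, "grayscale", t, m, "g")
  cat_c <- generate_categories(config, "color", gt, cc$observers, imgs)
  cat_g <- generate_categories(config, "grayscale", gt, gc_$observers, imgs)

  list(color = response_panel("color", cc$binary, cc$ratings, cat_c, gt),
       grayscale = response_panel("grayscale", gc_$binary, gc_$ratings,
                                  cat_g, gt),
       latent = data.frame(image_id = imgs, t = t, m = m,
                           stringsAsFactors = FALSE))
}

#' Synthetic backlit translucent cube image
#'
#' Renders a Beer-Lambert toy stimulus: a white backlight attenuated by a
#' colored absorbing medium whose thickness follows a pyramid (or custom)
#' profile. Transmittance is `exp(-sigma_e * d_k * thickness)` per channel,
#' with `d_k` the channel optical densities. Thin edges transmit nearly all
#' light (bright, desaturated); the thick center transmits little (dark,
#' saturated), so saturation and luminance correlate negatively over the
#' object mask - the signature of backlit translucency.
#'
#' @param size image side in pixels (default 64).
#' @param sigma_e extinction coefficient, > 0 (default 2).
#' @param densities length-3 per-channel optical densities of the medium
#'   (default a yellowish wax absorbing blue most).
#' @param thickness optional size x size matrix of thicknesses >= 0;
#'   default is a centered pyramid of peak height 1.
#' @param noise_sd SD of multiplicative log-normal pixel noise (default 0 =
#'   deterministic).
#' @param seed seed used when `noise_sd > 0`.
#' @return list with `image` (h x w x 3 sRGB array in \[0,1\]), `mask`
#'   (logical matrix, object pixels), `thickness`.
#' @export
generate_cube_image <- function(size = 64, sigma_e = 2,
                                densities = c(0.15, 0.35, 1.2),
                                thickness = NULL, noise_sd = 0, seed = 1) {
  if (sigma_e <= 0) stop("sigma_e must be positive")
  if (is.null(thickness)) {
    ax <- abs(seq(-1, 1, length.out = size))
    thickness <- outer(ax, ax, function(x, y) pmax(1 - pmax(x, y) / 0.92, 0))
  }
  if (any(thickness < 0)) stop("thickness must be non-negative")
  mask <- thickness > 0
  if (all(thickness == max(thickness))) {
    warning("flat thickness profile: saturation-luminance r is undefined")
  }
  trans <- vapply(densities, function(d) exp(-sigma_e * d * thickness),
                  matrix(0, nrow(thickness), ncol(thickness)))
  if (noise_sd > 0) {
    set.seed(seed)
    trans <- trans * exp(array(rnorm(length(trans), 0, noise_sd),
                               dim = dim(trans)))
    trans <- pmin(trans, 1)
  }
  lin <- trans
  lin[!mask] <- 0 # uniform black background outside the object
  img <- array(srgb_encode(as.vector(lin)), dim = dim(lin))
  list(image = img, mask = mask, thickness = thickness)
}
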