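#' Run configuration for the full analysis pipeline
#'
#' @param input either a directory of panel files (read with
#'   [read_panel()] for both conditions) or a [synthetic_config()].
#' @param label_threshold vote fraction for T/O labels (default 0.6).
#' @param kl_threshold divergence flag level in nats (default 1).
#' @param alpha per-test significance level (default 0.05).
#' @param alpha_pairs per-pair level for the attribute correlation matrix
#'   (default `bonferroni_alpha()` = 0.005).
#' @param perplexity t-SNE perplexity (default 15).
#' @param seed top-level seed; per-stage seeds derive from it so each stage
#'   is reproducible independently of the others.
#' @param run_tsne include the (slow) per-observer t-SNE stage (default
#'   `FALSE`).
#' @return list of class `run_config`.
#' @export
run_config <- function(input, label_threshold = 0.6, kl_threshold = 1,
                       alpha = 0.05, alpha_pairs = bonferroni_alpha(),
                       perplexity = 15, seed = 1, run_tsne = FALSE) {
  stopifnot(label_threshold > 0.5, label_threshold <= 1, kl_threshold >= 0,
            alpha > 0, alpha < 1)
  structure(list(input = input, label_threshold = label_threshold,
                 kl_threshold = kl_threshold, alpha = alpha,
                 alpha_pairs = alpha_pairs, perplexity = perplexity,
                 seed = seed, run_tsne = run_tsne),
            class = "run_config")
}

stage_seed <- function(seed, stage) {
  # independent per-stage streams; kept below 2^31
  (seed * 1000 + stage) %% .Machine$integer.max
}

#' Run the complete analysis pipeline
#'
#' Executes the analysis sequence - agreement statistics, rating
#' distribution statistics, perceptual-space analyses, and categorization
#' analyses - on a color/grayscale panel pair, and returns a single report
#' with every statistic and all seeds. Idempotent for a fixed config.
#'
#' @param config a [run_config()].
#' @return nested list report; convert with [write_report()].
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  if (inherits(config$input, "synthetic_config")) {
    pair <- generate_panel(config$input)
  } else {
    pair <- list(color = read_panel(config$input, "color"),
                 grayscale = read_panel(config$input, "grayscale"))
  }
  pc <- pair$color
  pg <- pair$grayscale
  report <- list(meta = list(
    seed = config$seed,
    label_threshold = config$label_threshold,
    kl_threshold = config$kl_threshold,
    kl_log_base = "e",
    alpha = config$alpha,
    alpha_pairs = config$alpha_pairs,
    n_images = length(pc$images),
    n_observers = length(pc$observers)))

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  report$agreement <- run_stage("agreement", {
    vc <- vote_counts(pc)
    vg <- vote_counts(pg)
    lc <- assign_label(vc, config$label_threshold)
    lg <- assign_label(vg, config$label_threshold)
    flips <- flip_table(lc, lg)
    kc <- kappa_matrix(pc)
    kg <- kappa_matrix(pg)
    list(percent_agreement = list(color = percent_agreement(vc),
                                  grayscale = percent_agreement(vg)),
         labels = list(color = table(lc$label), grayscale = table(lg$label)),
         flips = list(counts = flips$counts, n_flipped = flips$n_flipped),
         kappa = list(color = list(mean = kc$mean_kappa,
                                   level_fractions = kc$level_fractions),
                      grayscale = list(mean = kg$mean_kappa,
                                       level_fractions = kg$level_fractions)),
         kappa_mwu_p = mwu_test(kg$values[upper.tri(kg$values)],
                                kc$values[upper.tri(kc$values)],
                                alternative = "less")$p_value,
         rdm_mean = list(
           color = rdm_mean(hamming_rdm(pc$binary, "image")),
           grayscale = rdm_mean(hamming_rdm(pg$binary, "image"))))
  })

  report$ratings <- run_stage("ratings", {
    klt <- kl_table(pc, pg, config$kl_threshold)
    ks <- kl_summary(klt, config$kl_threshold)
    sk <- skewness_table(pc, pg)
    mrc <- mean_ratings(pc)
    mrg <- mean_ratings(pg)
    vc <- vote_counts(pc)
    vg <- vote_counts(pg)
    taus <- lapply(TLC_ATTRIBUTES, function(a) {
      list(color = tau_vs_opacity(
             mrc[[a]], vc$n_opaque[match(mrc$image_id, vc$image_id)],
             config$alpha),
           grayscale = tau_vs_opacity(
             mrg[[a]], vg$n_opaque[match(mrg$image_id, vg$image_id)],
             config$alpha))
    })
    names(taus) <- TLC_ATTRIBUTES
    list(kl_fraction_above = vapply(ks, `[[`, numeric(1), "fraction_above"),
         kl_mean = mean(klt$d_kl),
         skew_shift_sign = vapply(
           split(sk$d_s, sk$attribute)[TLC_ATTRIBUTES],
           function(d) mean(d > 0) - mean(d < 0), numeric(1)),
         tau_vs_opacity = taus,
         attribute_correlations = list(
           color = attribute_correlation_matrix(mrc, config$alpha_pairs),
           grayscale = attribute_correlation_matrix(mrg,
                                                    config$alpha_pairs)))
  })

  report$space <- run_stage("space", {
    pca_c <- pca_mean_ratings(mean_ratings(pc))
    pca_g <- pca_mean_ratings(mean_ratings(pg))
    preds_c <- panel_predictions(pc, seed = stage_seed(config$seed, 3))
    preds_g <- panel_predictions(pg, seed = stage_seed(config$seed, 4))
    acc <- function(preds) vapply(
      Filter(function(r) !isTRUE(r$skipped), preds),
      `[[`, numeric(1), "mean_accuracy")
    out <- list(
      pca_variance = list(color = pca_c$explained_variance_ratio,
                          grayscale = pca_g$explained_variance_ratio),
      pca_loadings = list(color = pca_c$loadings, grayscale = pca_g$loadings),
      accuracies = list(color = acc(preds_c), grayscale = acc(preds_g)),
      significant_counts = list(
        color = significant_attribute_counts(preds_c),
        grayscale = significant_attribute_counts(preds_g)))
    if (isTRUE(config$run_tsne)) {
      obs1 <- pc$observers[1]
      out$tsne_example <- tsne_embed(observer_rating_matrix(pc, obs1),
                                     perplexity = config$perplexity,
                                     seed = stage_seed(config$seed, 5))
    }
    out
  })

  if (nrow(pc$categories) > 0 && nrow(pg$categories) > 0 &&
      !is.null(pc$ground_truth)) {
    report$categorization <- run_stage("categorization", {
      scheme <- build_scheme()
      mc <- misjudgment_counts(pc$categories, scheme, pc$ground_truth)
      mg <- misjudgment_counts(pg$categories, scheme, pg$ground_truth)
      cmp <- compare_misjudgments(mc, mg)
      rdm_c <- category_person_rdm(pc$categories)
      rdm_g <- category_person_rdm(pg$categories)
      list(mean_misjudged = list(color = mean(mc$n_incorrect),
                                 grayscale = mean(mg$n_incorrect)),
           misjudgment_mwu_p = cmp$overall$p_value,
           food_nonfood = list(
             color = food_nonfood_table(pc$categories, scheme),
             grayscale = food_nonfood_table(pg$categories, scheme)),
           person_rdm_mean = list(color = rdm_mean(rdm_c),
                                  grayscale = rdm_mean(rdm_g)),
           person_rdm_mwu_p = compare_rdm_regions(rdm_c, rdm_g)$p_value)
    })
  }
  report$meta$elapsed_s <- as.numeric(difftime(Sys.time(), t0,
                                               units = "secs"))
  report
}

#' Write a pipeline report as JSON
#'
#' @param report a [run_all()] result.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(simplify_report(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

simplify_report <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    return(lapply(x, simplify_report))
  }
  if (is.table(x)) return(as.list(setNames(as.integer(x), names(x))))
  if (is.matrix(x)) return(apply(x, 1, as.list, simplify = FALSE))
  if (is.factor(x)) return(as.character(x))
  x
}
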