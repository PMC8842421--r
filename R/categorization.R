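# The closed 18-name material vocabulary shown to observers.
TLC_CATEGORIES <- c(
  "food in general", "food/cheese", "food/fruit/vegetables",
  "food/gummi/jelly", "food/meat/seafood", "food/candy/sugar",
  "food/shaved ice/ice cream/cream", "crystal/quartz/mineral/jade",
  "glass", "ivory", "marble/stone/concrete", "plastic/synthetic", "rubber",
  "soap", "wax", "wood", "chalk", "metal")

#' Material category vocabulary
#'
#' The 18 fine-grained material categories offered in the categorization
#' task.
#'
#' @return character vector of the 18 fine category names.
#' @export
tlc_categories <- function() TLC_CATEGORIES

#' Category regrouping scheme
#'
#' Builds the mapping from the 18 fine material categories to the eight major
#' groups used for misjudgment analysis, the discarded sparse categories, and
#' the food/non-food binarization. All seven `food/...` names collapse into
#' "food in general"; "ivory" merges into "marble/stone/concrete"; "rubber"
#' merges into "plastic/synthetic"; "chalk" and "wood" are discarded. Only
#' "food in general" counts as food.
#'
#' @return object of class `category_scheme` with elements `fine` (the 18
#'   names), `major` (the 8 group names), `fine_to_major` (named vector; `NA`
#'   for discarded fine categories), `discarded`, and `food_map` (named
#'   logical over major groups, `TRUE` = food).
#' @export
build_scheme <- function() {
  major <- c("food in general", "soap", "marble/stone/concrete/ivory",
             "glass", "crystal/quartz/mineral/jade",
             "plastic/synthetic/rubber", "wax", "metal")
  m <- setNames(rep(NA_character_, length(TLC_CATEGORIES)), TLC_CATEGORIES)
  m[startsWith(TLC_CATEGORIES, "food")] <- "food in general"
  m["soap"] <- "soap"
  m["marble/stone/concrete"] <- "marble/stone/concrete/ivory"
  m["ivory"] <- "marble/stone/concrete/ivory"
  m["glass"] <- "glass"
  m["crystal/quartz/mineral/jade"] <- "crystal/quartz/mineral/jade"
  m["plastic/synthetic"] <- "plastic/synthetic/rubber"
  m["rubber"] <- "plastic/synthetic/rubber"
  m["wax"] <- "wax"
  m["metal"] <- "metal"
  structure(
    list(fine = TLC_CATEGORIES,
         major = major,
         fine_to_major = m,
         discarded = c("chalk", "wood"),
         food_map = setNames(major == "food in general", major)),
    class = "category_scheme")
}

#' Map fine categories to major groups
#'
#' @param x character vector of fine (or already major) category names.
#' @param scheme a [build_scheme()] result.
#' @return character vector of major group names; discarded categories map to
#'   `NA`. Applying the map to its own output is a no-op (projection).
#' @export
to_major <- function(x, scheme = build_scheme()) {
  out <- ifelse(x %in% scheme$major, x,
                unname(scheme$fine_to_major[x]))
  unname(out)
}

#' Misjudgment counts against ground truth
#'
#' For every scored image, counts the observers whose chosen major group
#' differs from the ground-truth major group. Images whose ground truth falls
#' in a discarded category (chalk, wood) are excluded, as are images without
#' ground truth (with a warning).
#'
#' @param records data frame with columns `observer_id`, `image_id`,
#'   `category` (fine names).
#' @param scheme a [build_scheme()] result.
#' @param ground_truth named character vector image id -> fine category.
#' @return data frame with columns `image_id`, `truth_major`, `n_incorrect`,
#'   `n_observers`.
#' @export
misjudgment_counts <- function(records, scheme = build_scheme(),
                               ground_truth) {
  stopifnot(is.data.frame(records),
            all(c("observer_id", "image_id", "category") %in% names(records)))
  imgs <- sort(unique(records$image_id))
  no_gt <- setdiff(imgs, names(ground_truth))
  if (length(no_gt) > 0) {
    warning("excluding ", length(no_gt), " image(s) without ground truth")
    imgs <- setdiff(imgs, no_gt)
  }
  truth_major <- to_major(ground_truth[imgs], scheme)
  keep <- !is.na(truth_major)
  imgs <- imgs[keep]
  truth_major <- truth_major[keep]
  records <- records[records$image_id %in% imgs, , drop = FALSE]
  chosen_major <- to_major(records$category, scheme)
  wrong <- chosen_major != truth_major[match(records$image_id, imgs)]
  # a discarded choice (chalk/wood) cannot match any major-group truth
  wrong[is.na(wrong)] <- TRUE
  n_inc <- tapply(wrong, factor(records$image_id, levels = imgs), sum)
  n_obs <- tapply(wrong, factor(records$image_id, levels = imgs), length)
  data.frame(image_id = imgs,
             truth_major = unname(truth_major),
             n_incorrect = as.integer(n_inc),
             n_observers = as.integer(n_obs),
             stringsAsFactors = FALSE)
}

#' Compare misjudgment counts between conditions
#'
#' One-sided Mann-Whitney comparison of the per-image misjudgment counts of
#' two conditions, testing whether the second condition (typically grayscale)
#' has stochastically larger counts.
#'
#' @param counts_a,counts_b [misjudgment_counts()] outputs for the two
#'   conditions, matched on the image set.
#' @return list with per-major-group and overall [mwu_test()] results
#'   (alternative: a < b).
#' @export
compare_misjudgments <- function(counts_a, counts_b) {
  common <- intersect(counts_a$image_id, counts_b$image_id)
  a <- counts_a[match(common, counts_a$image_id), ]
  b <- counts_b[match(common, counts_b$image_id), ]
  overall <- mwu_test(a$n_incorrect, b$n_incorrect, alternative = "less")
  groups <- sort(unique(a$truth_major))
  per_group <- lapply(groups, function(g) {
    sel <- a$truth_major == g
    mwu_test(a$n_incorrect[sel], b$n_incorrect[sel], alternative = "less")
  })
  names(per_group) <- groups
  list(overall = overall, per_group = per_group)
}

#' Food versus non-food trial counts
#'
#' Binarizes each categorization trial into food / non-food via the major
#' grouping and stacks counts per image.
#'
#' @inheritParams misjudgment_counts
#' @return data frame with columns `image_id`, `n_food`, `n_nonfood`,
#'   `n_observers` (`n_food + n_nonfood = n_observers`; discarded-category
#'   choices count as non-food).
#' @export
food_nonfood_table <- function(records, scheme = build_scheme()) {
  major <- to_major(records$category, scheme)
  is_food <- !is.na(major) & scheme$food_map[major]
  imgs <- sort(unique(records$image_id))
  f <- factor(records$image_id, levels = imgs)
  nf <- tapply(is_food, f, sum)
  nt <- tapply(is_food, f, length)
  data.frame(image_id = imgs,
             n_food = as.integer(nf),
             n_nonfood = as.integer(nt - nf),
             n_observers = as.integer(nt),
             stringsAsFactors = FALSE)
}

#' Person-by-person categorical dissimilarity matrix
#'
#' Normalized Hamming distance between observers' fine-grained category
#' choices: the fraction of commonly categorized images on which two
#' observers chose different fine categories.
#'
#' @inheritParams misjudgment_counts
#' @return an `rdm` object (see [hamming_rdm()]) over observers.
#' @export
category_person_rdm <- function(records) {
  obs <- sort(unique(records$observer_id))
  imgs <- sort(unique(records$image_id))
  m <- matrix(NA_character_, length(imgs), length(obs),
              dimnames = list(imgs, obs))
  m[cbind(records$image_id, records$observer_id)] <- records$category
  if (anyNA(m)) {
    stop("all observers must categorize the same image set")
  }
  n <- length(obs)
  d <- matrix(0, n, n, dimnames = list(obs, obs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- mean(m[, i] != m[, j])
    }
  }
  new_rdm(d, axis = "observer")
}
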