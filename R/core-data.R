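#' Observer-response panels
#'
#' A `response_panel` holds all responses of one observer group for one
#' stimulus condition: the binary translucent/opaque classification of every
#' image by every observer, the five 6-point semantic attribute ratings, and
#' (optionally, for an observer subset) the material-category choices with
#' per-image ground truth.
#'
#' @param condition `"color"` or `"grayscale"`.
#' @param binary integer matrix of 0/1 (rows = images, columns = observers),
#'   with dimnames; 1 codes "translucent", 0 "opaque".
#' @param ratings data frame with columns `observer_id`, `image_id` and one
#'   integer column in 1..6 per attribute (see [tlc_attributes()]).
#' @param categories optional data frame with columns `observer_id`,
#'   `image_id`, `category`; categories must come from the closed 18-name
#'   vocabulary (see [tlc_categories()]). The categorization observer set may
#'   be a subset of the binary observer set.
#' @param ground_truth optional named character vector mapping image ids to
#'   ground-truth fine categories.
#' @return An object of class `response_panel`.
#' @export
response_panel <- function(condition, binary, ratings = NULL,
                           categories = NULL, ground_truth = NULL) {
  condition <- match.arg(condition, TLC_CONDITIONS)
  if (!is.matrix(binary) || is.null(rownames(binary)) ||
      is.null(colnames(binary))) {
    stop("`binary` must be a matrix with image rownames and observer colnames")
  }
  storage.mode(binary) <- "integer"
  if (!all(binary %in% c(0L, 1L))) {
    stop("binary responses must be 0 (opaque) or 1 (translucent)")
  }
  # canonical ordering fixes matrix axes across runs
  binary <- binary[order(rownames(binary)), order(colnames(binary)),
                   drop = FALSE]
  observers <- colnames(binary)
  images <- rownames(binary)
  if (anyDuplicated(observers)) stop("duplicate observer identifiers")
  if (anyDuplicated(images)) stop("duplicate image identifiers")

  if (!is.null(ratings) && nrow(ratings) > 0) {
    ratings <- validate_ratings(ratings, observers, images)
  } else {
    ratings <- empty_ratings()
  }
  if (!is.null(categories) && nrow(categories) > 0) {
    categories <- validate_categories(categories, observers, images)
  } else {
    categories <- empty_categories()
  }
  if (!is.null(ground_truth)) {
    bad <- setdiff(ground_truth, TLC_CATEGORIES)
    if (length(bad) > 0) {
      stop("unknown ground-truth category: ", paste(bad, collapse = ", "))
    }
    unknown <- setdiff(names(ground_truth), images)
    if (length(unknown) > 0) {
      stop("ground truth references unknown images: ",
           paste(head(unknown, 5), collapse = ", "))
    }
    ground_truth <- ground_truth[order(names(ground_truth))]
  }
  structure(
    list(condition = condition, observers = observers, images = images,
         binary = binary, ratings = ratings, categories = categories,
         ground_truth = ground_truth),
    class = "response_panel")
}

empty_ratings <- function() {
  out <- data.frame(observer_id = character(), image_id = character(),
                    stringsAsFactors = FALSE)
  for (a in TLC_ATTRIBUTES) out[[a]] <- integer()
  out
}

empty_categories <- function() {
  data.frame(observer_id = character(), image_id = character(),
             category = character(), stringsAsFactors = FALSE)
}

validate_ratings <- function(ratings, observers, images) {
  need <- c("observer_id", "image_id", TLC_ATTRIBUTES)
  miss <- setdiff(need, names(ratings))
  if (length(miss) > 0) {
    stop("ratings table missing column(s): ", paste(miss, collapse = ", "))
  }
  ratings <- ratings[, need]
  ratings$observer_id <- as.character(ratings$observer_id)
  ratings$image_id <- as.character(ratings$image_id)
  for (a in TLC_ATTRIBUTES) {
    v <- ratings[[a]]
    bad <- which(!(v %in% TLC_RATING_LEVELS))
    if (length(bad) > 0) {
      stop(sprintf("rating out of range 1..6 for attribute '%s' at row %d (observer %s, image %s): %s",
                   a, bad[1], ratings$observer_id[bad[1]],
                   ratings$image_id[bad[1]], v[bad[1]]))
    }
    ratings[[a]] <- as.integer(v)
  }
  unknown_obs <- setdiff(ratings$observer_id, observers)
  if (length(unknown_obs) > 0) {
    stop("ratings reference observers without binary responses: ",
         paste(head(unknown_obs, 5), collapse = ", "))
  }
  unknown_img <- setdiff(ratings$image_id, images)
  if (length(unknown_img) > 0) {
    stop("ratings reference images without binary responses: ",
         paste(head(unknown_img, 5), collapse = ", "))
  }
  key <- paste(ratings$observer_id, ratings$image_id)
  if (anyDuplicated(key)) {
    stop("duplicate (observer, image) rating rows, first: ",
         key[which(duplicated(key))[1]])
  }
  ratings[order(ratings$observer_id, ratings$image_id), , drop = FALSE]
}

validate_categories <- function(categories, observers, images) {
  need <- c("observer_id", "image_id", "category")
  miss <- setdiff(need, names(categories))
  if (length(miss) > 0) {
    stop("categories table missing column(s): ", paste(miss, collapse = ", "))
  }
  categories <- categories[, need]
  categories$observer_id <- as.character(categories$observer_id)
  categories$image_id <- as.character(categories$image_id)
  categories$category <- as.character(categories$category)
  bad <- which(!(categories$category %in% TLC_CATEGORIES))
  if (length(bad) > 0) {
    stop(sprintf("unknown material category at row %d (observer %s, image %s): '%s'",
                 bad[1], categories$observer_id[bad[1]],
                 categories$image_id[bad[1]], categories$category[bad[1]]))
  }
  unknown_obs <- setdiff(categories$observer_id, observers)
  if (length(unknown_obs) > 0) {
    stop("categorization observers must be a subset of binary observers; unknown: ",
         paste(head(unknown_obs, 5), collapse = ", "))
  }
  unknown_img <- setdiff(categories$image_id, images)
  if (length(unknown_img) > 0) {
    stop("categories reference images without binary responses: ",
         paste(head(unknown_img, 5), collapse = ", "))
  }
  categories[order(categories$observer_id, categories$image_id), ,
             drop = FALSE]
}

#' @export
print.response_panel <- function(x, ...) {
  cat(sprintf("<response_panel> condition=%s: %d images x %d observers\n",
              x$condition, length(x$images), length(x$observers)))
  cat(sprintf("  ratings rows: %d; category rows: %d (%d observers)\n",
              nrow(x$ratings), nrow(x$categories),
              length(unique(x$categories$observer_id))))
  invisible(x)
}

#' Read and write observer-response panels
#'
#' Panels are stored as UTF-8 comma-separated files in one directory:
#' `binary.csv` (`observer_id,image_id,condition,response`), `ratings.csv`
#' (`observer_id,image_id,condition,<five attribute columns>`), and optionally
#' `categories.csv` (`observer_id,image_id,condition,category`) and
#' `ground_truth.csv` (`image_id,category`). A single directory may hold both
#' conditions; `condition` selects which rows to load.
#'
#' @param path directory holding the panel files.
#' @param condition condition tag to load (`"color"` or `"grayscale"`).
#' @return [read_panel()] returns a validated [response_panel()];
#'   [write_panel()] invisibly returns `path`.
#' @export
read_panel <- function(path, condition) {
  condition <- match.arg(condition, TLC_CONDITIONS)
  bfile <- file.path(path, "binary.csv")
  if (!file.exists(bfile)) stop("missing file: ", bfile)
  bin <- read.csv(bfile, stringsAsFactors = FALSE)
  need <- c("observer_id", "image_id", "condition", "response")
  miss <- setdiff(need, names(bin))
  if (length(miss) > 0) {
    stop("binary.csv missing column(s): ", paste(miss, collapse = ", "))
  }
  bin <- bin[bin$condition == condition, , drop = FALSE]
  if (nrow(bin) == 0) stop("no binary rows for condition '", condition, "'")
  if (!all(bin$response %in% c(0L, 1L))) {
    bad <- which(!(bin$response %in% c(0L, 1L)))[1]
    stop(sprintf("binary response not in {0,1} at row %d (observer %s, image %s)",
                 bad, bin$observer_id[bad], bin$image_id[bad]))
  }
  observers <- sort(unique(as.character(bin$observer_id)))
  images <- sort(unique(as.character(bin$image_id)))
  mat <- matrix(NA_integer_, length(images), length(observers),
                dimnames = list(images, observers))
  mat[cbind(as.character(bin$image_id), as.character(bin$observer_id))] <-
    as.integer(bin$response)
  if (anyNA(mat)) {
    hole <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("incomplete binary panel: no response for image %s / observer %s",
                 images[hole[1]], observers[hole[2]]))
  }

  ratings <- NULL
  rfile <- file.path(path, "ratings.csv")
  if (file.exists(rfile)) {
    rat <- read.csv(rfile, stringsAsFactors = FALSE)
    if (!("condition" %in% names(rat))) {
      stop("ratings.csv missing column(s): condition")
    }
    ratings <- rat[rat$condition == condition, , drop = FALSE]
  }
  categories <- NULL
  cfile <- file.path(path, "categories.csv")
  if (file.exists(cfile)) {
    cat_ <- read.csv(cfile, stringsAsFactors = FALSE)
    if (!("condition" %in% names(cat_))) {
      stop("categories.csv missing column(s): condition")
    }
    categories <- cat_[cat_$condition == condition, , drop = FALSE]
  }
  ground_truth <- NULL
  gfile <- file.path(path, "ground_truth.csv")
  if (file.exists(gfile)) {
    gt <- read.csv(gfile, stringsAsFactors = FALSE)
    ground_truth <- setNames(as.character(gt$category),
                             as.character(gt$image_id))
  }
  response_panel(condition, mat, ratings, categories, ground_truth)
}

#' @param panel a [response_panel()].
#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "response_panel"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  bin <- expand.grid(image_id = panel$images, observer_id = panel$observers,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  bin$condition <- panel$condition
  bin$response <- as.vector(panel$binary[cbind(bin$image_id, bin$observer_id)])
  bin <- bin[order(bin$observer_id, bin$image_id),
             c("observer_id", "image_id", "condition", "response")]
  append_or_write(bin, file.path(path, "binary.csv"), panel$condition)
  if (nrow(panel$ratings) > 0) {
    rat <- panel$ratings
    rat$condition <- panel$condition
    rat <- rat[, c("observer_id", "image_id", "condition", TLC_ATTRIBUTES)]
    append_or_write(rat, file.path(path, "ratings.csv"), panel$condition)
  }
  if (nrow(panel$categories) > 0) {
    cat_ <- panel$categories
    cat_$condition <- panel$condition
    cat_ <- cat_[, c("observer_id", "image_id", "condition", "category")]
    append_or_write(cat_, file.path(path, "categories.csv"), panel$condition)
  }
  if (!is.null(panel$ground_truth)) {
    gt <- data.frame(image_id = names(panel$ground_truth),
                     category = unname(panel$ground_truth),
                     stringsAsFactors = FALSE)
    write.csv(gt, file.path(path, "ground_truth.csv"), row.names = FALSE)
  }
  invisible(path)
}

# Replace rows of this condition while preserving the other condition's rows,
# so one directory can hold a color/grayscale panel pair.
append_or_write <- function(df, file, condition) {
  if (file.exists(file)) {
    old <- read.csv(file, stringsAsFactors = FALSE)
    if (identical(sort(names(old)), sort(names(df)))) {
      old <- old[old$condition != condition, names(df), drop = FALSE]
      df <- rbind(old, df)
      df <- df[order(df$condition, df$observer_id, df$image_id), ]
    }
  }
  write.csv(df, file, row.names = FALSE)
}

#' Per-image vote counts from a panel
#'
#' Tallies, for each image, how many observers classified it as translucent
#' versus opaque.
#'
#' @param panel a [response_panel()].
#' @return data frame with columns `image_id`, `n_translucent`, `n_opaque`,
#'   `n_total`, one row per image in canonical order.
#' @export
vote_counts <- function(panel) {
  stopifnot(inherits(panel, "response_panel"))
  nt <- rowSums(panel$binary)
  data.frame(image_id = panel$images,
             n_translucent = as.integer(nt),
             n_opaque = as.integer(ncol(panel$binary) - nt),
             n_total = ncol(panel$binary),
             stringsAsFactors = FALSE)
}

#' Mean attribute ratings per image
#'
#' @param panel a [response_panel()].
#' @return data frame, one row per rated image, columns `image_id` plus the
#'   five attribute means across observers.
#' @export
mean_ratings <- function(panel) {
  stopifnot(inherits(panel, "response_panel"))
  if (nrow(panel$ratings) == 0) stop("panel has no ratings")
  agg <- aggregate(panel$ratings[TLC_ATTRIBUTES],
                   by = list(image_id = panel$ratings$image_id), FUN = mean)
  agg[order(agg$image_id), , drop = FALSE]
}

#' One observer's ratings as an image-by-attribute matrix
#'
#' @param panel a [response_panel()].
#' @param observer observer identifier.
#' @return integer matrix (images x 5 attributes) of that observer's ratings,
#'   rows named by image id.
#' @export
observer_rating_matrix <- function(panel, observer) {
  stopifnot(inherits(panel, "response_panel"))
  sub <- panel$ratings[panel$ratings$observer_id == observer, , drop = FALSE]
  if (nrow(sub) == 0) stop("no ratings for observer ", observer)
  m <- as.matrix(sub[, TLC_ATTRIBUTES])
  rownames(m) <- sub$image_id
  m
}
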