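#' Write a study to delimited files
#'
#' Emits the CSV trio consumed by [read_study()]: \code{transects.csv}
#' (t, k, platform, x1, y1, x2, y2), \code{sightings.csv} (individual_id,
#' t, k, x, y, group; blank group = unknown), and \code{covariates.csv}
#' (long format: g, x_center, y_center, t, one column per covariate),
#' plus \code{grid.csv} (name,value pairs: n_x, n_y, side, origin_x,
#' origin_y, T, K1..KT) and \code{mask.csv} when the grid is masked. If
#' \code{truth} is supplied (from [simulate_study()]), truth sidecar files
#' \code{truth_*.csv} are written as well; they are never read by the
#' model-fitting loader.
#'
#' @param study an \code{scr_study}.
#' @param dir output directory (created if needed).
#' @param truth optional truth list from [simulate_study()].
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- study$grid
  utils::write.csv(study$segments, file.path(dir, "transects.csv"),
                   row.names = FALSE)
  sg <- study$detections
  sg$group <- ifelse(is.na(study$groups[sg$individual]), "",
                     study$groups[sg$individual])
  names(sg)[1] <- "individual_id"
  utils::write.csv(sg, file.path(dir, "sightings.csv"), row.names = FALSE)
  Tt <- study$T_periods
  cv <- do.call(rbind, lapply(seq_len(Tt), function(t) {
    d <- data.frame(g = seq_len(g$G), x_center = g$centers[, 1],
                    y_center = g$centers[, 2], t = t)
    cbind(d, as.data.frame(matrix(study$X[, , t], g$G, dim(study$X)[2],
                                  dimnames = list(NULL,
                                                  dimnames(study$X)[[2]]))))
  }))
  utils::write.csv(cv, file.path(dir, "covariates.csv"), row.names = FALSE)
  meta <- data.frame(
    name = c("n_x", "n_y", "side", "origin_x", "origin_y", "T",
             paste0("K", seq_len(Tt))),
    value = c(g$n_x, g$n_y, g$side, g$origin[1], g$origin[2], Tt, study$K))
  utils::write.csv(meta, file.path(dir, "grid.csv"), row.names = FALSE)
  if (!all(g$valid))
    utils::write.csv(data.frame(cell = seq_along(g$valid), valid = g$valid),
                     file.path(dir, "mask.csv"), row.names = FALSE)
  if (!is.null(truth)) {
    utils::write.csv(as.data.frame(truth$z),
                     file.path(dir, "truth_z.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(truth$s),
                     file.path(dir, "truth_s.csv"), row.names = FALSE)
    utils::write.csv(data.frame(individual = seq_along(truth$group),
                                group = truth$group),
                     file.path(dir, "truth_group.csv"), row.names = FALSE)
    utils::write.csv(truth$locations, file.path(dir, "truth_locations.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Load and validate a study from delimited files
#'
#' Reads the CSV trio written by [write_study()] (or prepared by hand in
#' the same layout), applies the documented filtering rules, and validates
#' the result. Rules and checks:
#' \itemize{
#'   \item at most one detection per individual per occasion: duplicate
#'     records within an (individual, t, k) keep the first row in file
#'     order, with a warning (with no time-of-day column, file order is the
#'     best available proxy for "earliest");
#'   \item a detection on an occasion with no surveyed transects is a hard
#'     error (it cannot have been made);
#'   \item detections outside the grid bounding box (or in masked pixels)
#'     are errors, reported with their row numbers;
#'   \item group labels must come from the set of labels seen in the file
#'     (or \code{group_labels} if supplied); blank = unknown;
#'   \item optional \code{max_dist} drops detections whose mindist to the
#'     occasion's transects exceeds it (outlier guard), with a warning;
#'   \item \code{scale} divides all coordinates (transects and sightings)
#'     on load, for converting e.g. km to the model's scaled units.
#' }
#' Covariates are standardized on load (pooling over pixels and periods);
#' columns listed in \code{square} get squared companions.
#'
#' @param dir directory containing the study files.
#' @param group_labels optional character vector fixing the group-label
#'   universe (and hence V and group indexing).
#' @param square covariate names to square (default none: the simulator
#'   already writes its squared columns).
#' @param max_dist optional maximum mindist filter.
#' @param scale coordinate scale divisor applied on load (default 1).
#' @return An \code{scr_study} list.
#' @export
read_study <- function(dir, group_labels = NULL, square = NULL,
                       max_dist = NULL, scale = 1) {
  rd <- function(f) utils::read.csv(file.path(dir, f),
                                    stringsAsFactors = FALSE)
  meta <- rd("grid.csv")
  mval <- function(nm) as.numeric(meta$value[match(nm, meta$name)])
  Tt <- as.integer(mval("T"))
  K <- as.integer(sapply(paste0("K", seq_len(Tt)), mval))
  mask <- NULL
  if (file.exists(file.path(dir, "mask.csv")))
    mask <- rd("mask.csv")$valid
  grid <- ss_grid(mval("n_x"), mval("n_y"), mval("side") / scale,
                  c(mval("origin_x"), mval("origin_y")) / scale, mask)
  segments <- rd("transects.csv")
  for (cc in c("x1", "y1", "x2", "y2"))
    segments[[cc]] <- segments[[cc]] / scale
  if (any(segments$x1 == segments$x2 & segments$y1 == segments$y2))
    stop("zero-length transect segment in transects.csv")
  sg <- rd("sightings.csv")
  if (is.null(sg$group)) sg$group <- ""
  sg$group <- as.character(sg$group)
  sg$group[is.na(sg$group)] <- ""
  sg$x <- sg$x / scale; sg$y <- sg$y / scale
  sg$.row <- seq_len(nrow(sg))

  # one detection per individual per occasion: keep first in file order
  key <- paste(sg$individual_id, sg$t, sg$k)
  if (anyDuplicated(key)) {
    warning(sprintf(
      "%d duplicate same-occasion detections dropped (kept first record)",
      sum(duplicated(key))))
    sg <- sg[!duplicated(key), , drop = FALSE]
  }

  # detections must fall on occasions with effort, inside the state-space
  seg_key <- paste(segments$t, segments$k)
  bad <- !(paste(sg$t, sg$k) %in% seg_key)
  if (any(bad))
    stop("detections on occasions with no surveyed transects, rows: ",
         paste(sg$.row[bad], collapse = ", "))
  pix <- tryCatch(pixel_of_point(sg$x, sg$y, grid), error = function(e) e)
  if (inherits(pix, "error")) {
    ok <- rep(TRUE, nrow(sg))
    for (i in seq_len(nrow(sg)))
      ok[i] <- !inherits(tryCatch(pixel_of_point(sg$x[i], sg$y[i], grid),
                                  error = function(e) e), "error")
    stop("detections outside the state-space, rows: ",
         paste(sg$.row[!ok], collapse = ", "))
  }

  if (!is.null(max_dist)) {
    far <- rep(FALSE, nrow(sg))
    for (i in seq_len(nrow(sg))) {
      segs <- segments[segments$t == sg$t[i] & segments$k == sg$k[i], ]
      far[i] <- min_distance_to_transects(sg$x[i], sg$y[i],
                                          segs)$distance > max_dist
    }
    if (any(far)) {
      warning(sprintf("%d detections beyond max_dist %g dropped",
                      sum(far), max_dist))
      sg <- sg[!far, , drop = FALSE]
    }
  }

  ids <- unique(sg$individual_id)
  n <- length(ids)
  grp_raw <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    lb <- setdiff(unique(sg$group[sg$individual_id == ids[i]]), "")
    lb <- lb[!is.na(lb)]
    if (length(lb) > 1)
      stop("conflicting group labels for individual ", ids[i])
    if (length(lb) == 1) grp_raw[i] <- lb
  }
  seen <- sort(unique(grp_raw[!is.na(grp_raw)]))
  if (is.null(group_labels)) group_labels <- if (length(seen)) seen else "g1"
  if (length(bad_lab <- setdiff(seen, group_labels)))
    stop("unknown group labels: ", paste(bad_lab, collapse = ", "))

  detections <- data.frame(individual = match(sg$individual_id, ids),
                           t = sg$t, k = sg$k, x = sg$x, y = sg$y)
  cv <- rd("covariates.csv")
  cov_cols <- setdiff(names(cv), c("g", "x_center", "y_center", "t"))
  X <- array(NA_real_, dim = c(grid$G, length(cov_cols), Tt))
  for (t in seq_len(Tt)) {
    block <- cv[cv$t == t, , drop = FALSE]
    block <- block[order(block$g), , drop = FALSE]
    if (nrow(block) != grid$G)
      stop("covariates.csv must have one row per pixel per period")
    X[, , t] <- as.matrix(block[, cov_cols, drop = FALSE])
  }
  X <- covariate_stack(X, names = cov_cols, square = square)

  structure(list(
    grid = grid, T_periods = Tt, K = K, segments = segments,
    detections = detections, n = n, groups = grp_raw,
    group_labels = group_labels, V = length(group_labels), X = X
  ), class = "scr_study")
}

#' Augment observed capture histories
#'
#' Data augmentation: pad the n observed individuals with M - n
#' hypothetical all-zero capture histories, which makes first-period
#' abundance a sum of latent presence indicators under an implicit discrete
#' Uniform(0, M) prior. Returns the augmented index map and group vector
#' (augmented individuals always have latent group).
#'
#' @param study an \code{scr_study}.
#' @param M augmented population size (must exceed \code{study$n}; guidance:
#'   at least 1.5 x n, raised if the posterior of N_t crowds M).
#' @return A list with \code{M}, \code{n}, \code{group} (length-M integer,
#'   NA where latent) and \code{observed} (logical length M).
#' @export
augment_histories <- function(study, M) {
  n <- study$n
  if (M < n)
    stop(sprintf(
      "M = %d but %d individuals were observed; raise M (guidance: >= 1.5 n)",
      M, n))
  if (M == n)
    warning("M equals the observed count; abundance is truncated at M, ",
            "raise M for usable inference")
  group <- rep(NA_integer_, M)
  group[seq_len(n)] <- match(study$groups, study$group_labels)
  list(M = as.integer(M), n = n, group = group,
       observed = seq_len(M) <= n)
}
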