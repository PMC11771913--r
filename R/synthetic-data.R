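# Synthetic crash data: clustered point patterns plus a spatial lag probit
# data-generating process with stored ground truth.

#' Declare a categorical covariate for the synthetic crash-table schema
#'
#' Categorical covariates are coded as small non-negative integers
#' (`0` conventionally the "Unknown"/"Other" base level), mirroring the
#' integer coding used in crash-registry summary tables.
#'
#' @param name Column name.
#' @param probs Named or unnamed numeric vector of level probabilities; must
#'   sum to 1. Level codes are `0:(length(probs) - 1)` unless `codes` is given.
#' @param codes Optional integer codes, one per probability.
#' @return A covariate-spec list used by [synthetic_config()].
#' @export
cov_categorical <- function(name, probs, codes = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.numeric(probs))
  if (abs(sum(probs) - 1) > 1e-8) {
    stop("level probabilities for '", name, "' must sum to 1 (got ",
         format(sum(probs)), ")")
  }
  if (is.null(codes)) codes <- seq_along(probs) - 1L
  stopifnot(length(codes) == length(probs))
  structure(list(name = name, type = "categorical",
                 probs = as.numeric(probs), codes = as.integer(codes)),
            class = "cov_spec")
}

#' Declare a continuous covariate for the synthetic crash-table schema
#'
#' @param name Column name.
#' @param mean,sd Normal distribution parameters on the covariate's scale.
#' @param round_min Optional: round draws to integers and floor at this value
#'   (used for counts such as total vehicles involved).
#' @return A covariate-spec list used by [synthetic_config()].
#' @export
cov_continuous <- function(name, mean = 0, sd = 1, round_min = NULL) {
  stopifnot(is.character(name), length(name) == 1L, sd >= 0)
  structure(list(name = name, type = "continuous", mean = mean, sd = sd,
                 round_min = round_min),
            class = "cov_spec")
}

#' Default covariate schema emulating a crash-registry variable summary
#'
#' Marginal level proportions approximate the category structure of a Nevada
#' older-driver crash registry (crash type, at-fault/not-at-fault vehicle
#' descriptors, road, weather and lighting conditions, total vehicles).
#' Columns are drawn independently of each other; a registry's joint
#' dependence structure is not emulated.
#'
#' @return A list of covariate specs.
#' @export
default_covariate_schema <- function() {
  list(
    cov_categorical("crash_type",
      c(0.0007, 0.4294, 0.0040, 0.0123, 0.2997, 0.0361, 0.2178)),
    cov_categorical("veh1_type",
      c(0.0879, 0.5454, 0.1468, 0.1820, 0.0379)),
    cov_categorical("veh1_action",
      c(0.0454, 0.0049, 0.0325, 0.5708, 0.0165, 0.0045, 0.0063, 0.1816,
        0.0507, 0.0121, 0.0747)),
    cov_categorical("veh1_driver_condition",
      c(0.1368, 0.6166, 0.1424, 0.0168, 0.0096, 0.0456, 0.0036, 0.0286)),
    cov_categorical("veh1_condition",
      c(0.0743, 0.0896, 0.0259, 0.3464, 0.0633, 0.1089, 0.0145, 0.0381,
        0.0841, 0.0672, 0.0877)),
    cov_categorical("veh2_type",
      c(0.0290, 0.4264, 0.1211, 0.1793, 0.2442)),
    cov_categorical("veh2_driver_age",
      c(0.0451, 0.2747, 0.1480, 0.4553, 0.0769)),
    cov_categorical("veh2_action",
      c(0.2364, 0.0006, 0.0045, 0.4541, 0.0016, 0.0006, 0.2375, 0.0474,
        0.0112, 0.0012, 0.0049)),
    cov_categorical("veh2_driver_condition",
      c(0.2634, 0.7250, 0.0076, 0.0028, 0.0002, 0.0001, 0.0001, 0.0008)),
    cov_categorical("veh2_condition",
      c(0.0744, 0.0897, 0.0258, 0.3463, 0.0634, 0.1090, 0.0144, 0.0380,
        0.0842, 0.0673, 0.0875)),
    cov_categorical("road_condition", c(0.0025, 0.9585, 0.0378, 0.0012)),
    cov_categorical("weather_condition",
      c(0.0005, 0.9914, 0.0039, 0.0004, 0.0038)),
    cov_categorical("lighting_condition",
      c(0.0003, 0.3661, 0.6061, 0.0275)),
    cov_continuous("total_vehicles", mean = 1.98, sd = 0.71, round_min = 1)
  )
}

#' Default regression coefficients for the synthetic crash DGP
#'
#' Intercept plus one coefficient per column of [default_covariate_schema()],
#' in schema order. Coefficients of the nine significant predictors take the
#' magnitudes reported for an older-driver spatial probit fit in Clark County,
#' Nevada (e.g. crash type -0.106, road condition -0.534, intercept 1.541);
#' the remaining predictors carry zero effect.
#'
#' @return Named numeric vector, intercept first.
#' @export
default_beta <- function() {
  c("(Intercept)"           =  1.541,
    crash_type              = -0.106,
    veh1_type               = -0.063,
    veh1_action             =  0.146,
    veh1_driver_condition   =  0.045,
    veh1_condition          = -0.040,
    veh2_type               =  0.000,
    veh2_driver_age         =  0.000,
    veh2_action             = -0.020,
    veh2_driver_condition   =  0.000,
    veh2_condition          = -0.028,
    road_condition          = -0.534,
    weather_condition       = -0.055,
    lighting_condition      =  0.000,
    total_vehicles          =  0.000)
}

#' Specify a synthetic crash-data generating process
#'
#' Defines the spatial geometry (planted circular hotspots over a uniform
#' background) and the outcome model: a spatial lag binary probit
#' `Y* = rho W Y* + X beta + eps`, `eps ~ N(0, I)`, `y = 1(Y* > 0)`.
#' The error variance is fixed at 1 for probit identification and is not
#' configurable.
#'
#' @param hotspots Data frame with columns `x`, `y` (disc centres), `radius`
#'   and `n` (points per disc), all in the planar coordinate units of
#'   `bounding_box`. May have zero rows.
#' @param background_count Number of background (noise) points drawn
#'   uniformly over the bounding box.
#' @param bounding_box Numeric `c(xmin, ymin, xmax, ymax)`.
#' @param beta Coefficient vector, intercept first; length must be one more
#'   than the number of covariates in `covariates`.
#' @param rho Spatial dependence scalar; must lie strictly inside the
#'   support implied by the row-standardised weight matrix.
#' @param covariates List of covariate specs ([cov_categorical()],
#'   [cov_continuous()]).
#' @param weights Neighbour rule for the DGP: `list(rule = "knn", k = 5)` or
#'   `list(rule = "distance_band", threshold = <radius>)`.
#' @param encoding How categorical covariates enter the design matrix of the
#'   DGP: `"ordinal"` (integer codes as-is, the default, mirroring
#'   single-coefficient-per-variable registry practice) or `"dummy"`.
#' @param age_range Driver ages are drawn uniformly (integer years) on this
#'   range, so the older-driver filter is exercised on synthetic tables.
#' @param seed Integer seed controlling all randomness of the generator.
#' @return An object of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config(
#'   hotspots = data.frame(x = c(2000, 8000), y = c(2000, 8000),
#'                         radius = 200, n = 60),
#'   background_count = 80, seed = 1)
#' @export
synthetic_config <- function(hotspots = data.frame(x = c(2500, 7500, 5000),
                                                   y = c(2500, 7500, 2500),
                                                   radius = 200, n = 60),
                             background_count = 120,
                             bounding_box = c(0, 0, 10000, 10000),
                             beta = default_beta(),
                             rho = 0.5,
                             covariates = default_covariate_schema(),
                             weights = list(rule = "knn", k = 5),
                             encoding = c("ordinal", "dummy"),
                             age_range = c(55, 95),
                             seed = 1L) {
  encoding <- match.arg(encoding)
  hotspots <- as.data.frame(hotspots)
  if (nrow(hotspots) > 0) {
    stopifnot(all(c("x", "y", "radius", "n") %in% names(hotspots)))
    if (any(hotspots$radius <= 0)) stop("hotspot radii must be > 0")
  }
  stopifnot(length(bounding_box) == 4, is.numeric(bounding_box))
  if (bounding_box[3] <= bounding_box[1] || bounding_box[4] <= bounding_box[2]) {
    stop("degenerate bounding box")
  }
  # every hotspot disc must sit fully inside the bounding box
  if (nrow(hotspots) > 0) {
    inside <- hotspots$x - hotspots$radius >= bounding_box[1] &
      hotspots$x + hotspots$radius <= bounding_box[3] &
      hotspots$y - hotspots$radius >= bounding_box[2] &
      hotspots$y + hotspots$radius <= bounding_box[4]
    if (!all(inside)) {
      stop("geometry error: hotspot disc(s) ",
           paste(which(!inside), collapse = ", "),
           " not contained in the bounding box")
    }
  }
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)")
  nm <- vapply(covariates, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate covariate names")
  if (length(beta) != length(covariates) + 1L) {
    stop("beta must have length ", length(covariates) + 1L,
         " (intercept + one per covariate), got ", length(beta))
  }
  structure(list(hotspots = hotspots,
                 background_count = as.integer(background_count),
                 n_points = as.integer(sum(hotspots$n) + background_count),
                 bounding_box = as.numeric(bounding_box),
                 beta = as.numeric(beta), beta_names = names(beta),
                 rho = rho, covariates = covariates, weights = weights,
                 encoding = encoding, age_range = age_range,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic crash DGP:", nrow(x$hotspots), "hotspot(s) +",
      x$background_count, "background points =", x$n_points, "points\n")
  cat("  rho =", x$rho, "| weights:", x$weights$rule, "|",
      length(x$covariates), "covariates | seed", x$seed, "\n")
  invisible(x)
}

runif_disc <- function(n, cx, cy, radius) {
  # uniform on the disc: sqrt-radius transform
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Generate a clustered point pattern with known hotspot membership
#'
#' Points inside each hotspot are uniform on the disc; background points are
#' uniform over the bounding box. The true cluster label (hotspot index, or
#' 0 for background noise) is recorded per point.
#'
#' @param config A [synthetic_config()].
#' @return List with `points` (data frame: `id`, `x`, `y`) and `truth`
#'   (data frame: `id`, `cluster` with 0 = background noise).
#' @export
generate_point_pattern <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  hs <- config$hotspots
  coords <- matrix(numeric(0), ncol = 2)
  labels <- integer(0)
  if (nrow(hs) > 0) {
    for (h in seq_len(nrow(hs))) {
      coords <- rbind(coords, runif_disc(hs$n[h], hs$x[h], hs$y[h], hs$radius[h]))
      labels <- c(labels, rep.int(h, hs$n[h]))
    }
  }
  bb <- config$bounding_box
  nb <- config$background_count
  if (nb > 0) {
    coords <- rbind(coords, cbind(x = stats::runif(nb, bb[1], bb[3]),
                                  y = stats::runif(nb, bb[2], bb[4])))
    labels <- c(labels, rep.int(0L, nb))
  }
  n <- nrow(coords)
  list(points = data.frame(id = seq_len(n), x = coords[, 1], y = coords[, 2]),
       truth = data.frame(id = seq_len(n), cluster = labels))
}

draw_covariates <- function(config, n) {
  if (length(config$covariates) == 0) {
    return(as.data.frame(matrix(numeric(0), nrow = n, ncol = 0)))
  }
  cols <- lapply(config$covariates, function(s) {
    if (s$type == "categorical") {
      sample(s$codes, n, replace = TRUE, prob = s$probs)
    } else {
      v <- stats::rnorm(n, s$mean, s$sd)
      if (!is.null(s$round_min)) v <- pmax(round(v), s$round_min)
      v
    }
  })
  names(cols) <- vapply(config$covariates, function(s) s$name, character(1))
  as.data.frame(cols)
}

dgp_design <- function(config, covs) {
  # design matrix for the generating model (intercept first)
  if (config$encoding == "ordinal") {
    X <- cbind(1, as.matrix(covs))
  } else {
    pieces <- lapply(seq_along(config$covariates), function(j) {
      s <- config$covariates[[j]]
      if (s$type != "categorical") return(matrix(covs[[j]], ncol = 1,
                                                 dimnames = list(NULL, s$name)))
      lev <- sort(s$codes)[-1]  # base = smallest code
      m <- vapply(lev, function(l) as.numeric(covs[[j]] == l),
                  numeric(nrow(covs)))
      colnames(m) <- paste0(s$name, "_", lev)
      m
    })
    X <- cbind(1, do.call(cbind, pieces))
  }
  colnames(X)[1] <- "(Intercept)"
  X
}

#' Generate a crash table from a spatial lag probit data-generating process
#'
#' Builds the point pattern, draws covariates per schema, constructs the
#' spatial weight matrix by the configured neighbour rule, row-standardises
#' it, and solves the latent field `(I - rho W) Y* = X beta + eps` by a dense
#' solve (exact at the scale of a few thousand observations). The binary
#' severity outcome is `1(Y* > 0)`; latent values, true labels and true
#' parameters are returned as ground truth.
#'
#' @param config A [synthetic_config()]. Under dummy encoding `beta` must
#'   match the expanded design's column count.
#' @return List with `table` (a crash table data frame: `id`, `x`, `y`,
#'   `severity`, `age`, covariate columns) and `truth` (list: `cluster`,
#'   `beta`, `rho`, `ystar`, `weights`).
#' @export
generate_crash_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  pat <- generate_point_pattern(config)   # seeds the RNG stream
  n <- nrow(pat$points)
  covs <- draw_covariates(config, n)
  age <- sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)
  X <- dgp_design(config, covs)
  if (ncol(X) != length(config$beta)) {
    stop("beta has length ", length(config$beta), " but the ",
         config$encoding, "-encoded design has ", ncol(X), " columns")
  }
  eta <- drop(X %*% config$beta)
  eps <- stats::rnorm(n)
  if (config$rho == 0) {
    ystar <- eta + eps
    Wm <- NULL
  } else {
    coords <- as.matrix(pat$points[, c("x", "y")])
    Wm <- switch(config$weights$rule,
      knn = knn_weights(coords, k = config$weights$k),
      distance_band = distance_band_weights(coords, config$weights$threshold),
      stop("unknown weights rule: ", config$weights$rule))
    Wm <- row_standardize(Wm)
    sup <- Wm$rho_support
    if (config$rho <= sup[1] || config$rho >= sup[2]) {
      stop("rho = ", config$rho, " outside the support (",
           format(sup[1], digits = 4), ", ", format(sup[2], digits = 4),
           ") of the row-standardized weights")
    }
    S <- Matrix::Diagonal(n) - config$rho * Wm$W
    lndet <- sum(log(Mod(1 - config$rho * complex(real = Wm$eigen_re,
                                                  imaginary = Wm$eigen_im))))
    if (!is.finite(lndet)) {
      stop("(I - rho W) numerically singular at rho = ", config$rho,
           "; an eigenvalue 1/lambda equals rho")
    }
    ystar <- as.numeric(Matrix::solve(S, eta + eps))
  }
  tab <- data.frame(id = pat$points$id, x = pat$points$x, y = pat$points$y,
                    severity = as.integer(ystar > 0), age = age)
  tab <- cbind(tab, covs)
  class(tab) <- c("crash_table", "data.frame")
  list(table = tab,
       truth = list(cluster = pat$truth$cluster,
                    beta = stats::setNames(config$beta, colnames(X)),
                    rho = config$rho, ystar = ystar, weights = Wm))
}

#' Write / read a crash table as a delimited text file
#'
#' Tab-separated with a header row; columns `id`, `x`, `y`, `severity`,
#' `age`, then covariates.
#'
#' @param table A crash table data frame.
#' @param path Output file path.
#' @export
write_crash_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_crash_table
#' @export
read_crash_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(tab) <- c("crash_table", "data.frame")
  tab
}

#' Write / read ground truth as a structured text sidecar
#'
#' Per-record rows (`id`, `true_cluster`, `latent_ystar`) keyed by record id,
#' preceded by `#`-prefixed metadata lines carrying the true `beta` and `rho`.
#'
#' @param truth The `truth` element returned by [generate_crash_table()].
#' @param ids Record ids, aligned with `truth$ystar`.
#' @param path Output file path.
#' @export
write_ground_truth <- function(truth, ids, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# rho\t", format(truth$rho, digits = 17)), con)
  writeLines(paste0("# beta\t",
                    paste(names(truth$beta), format(truth$beta, digits = 17),
                          sep = "=", collapse = "\t")), con)
  df <- data.frame(id = ids, true_cluster = truth$cluster,
                   latent_ystar = truth$ystar)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# ", lines, value = TRUE)
  rho <- as.numeric(sub("^# rho\t", "", grep("^# rho\t", meta, value = TRUE)))
  bline <- sub("^# beta\t", "", grep("^# beta\t", meta, value = TRUE))
  kv <- strsplit(strsplit(bline, "\t")[[1]], "=", fixed = TRUE)
  beta <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
                          vapply(kv, `[`, character(1), 1))
  df <- utils::read.table(textConnection(lines[!startsWith(lines, "# ")]),
                          header = TRUE, sep = "\t")
  list(cluster = df$true_cluster, beta = beta, rho = rho,
       ystar = df$latent_ystar, ids = df$id)
}

#' Read / write a synthetic-DGP configuration as YAML
#'
#' @param path YAML file describing the fields of [synthetic_config()];
#'   covariates are given as a list of `{name, type, probs|mean/sd}` entries.
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  covs <- if (is.null(y$covariates)) default_covariate_schema() else
    lapply(y$covariates, function(e) {
      if (e$type == "categorical") {
        cov_categorical(e$name, unlist(e$probs))
      } else {
        cov_continuous(e$name, e$mean %||% 0, e$sd %||% 1,
                       round_min = e$round_min)
      }
    })
  beta <- if (is.null(y$beta)) default_beta() else unlist(y$beta)
  hs <- if (is.null(y$hotspots)) data.frame(x = numeric(0), y = numeric(0),
                                            radius = numeric(0), n = integer(0))
        else do.call(rbind, lapply(y$hotspots, as.data.frame))
  synthetic_config(
    hotspots = hs,
    background_count = y$background_count %||% 0L,
    bounding_box = unlist(y$bounding_box %||% c(0, 0, 10000, 10000)),
    beta = beta, rho = y$rho %||% 0.5, covariates = covs,
    weights = y$weights %||% list(rule = "knn", k = 5),
    encoding = y$encoding %||% "ordinal",
    age_range = unlist(y$age_range %||% c(55, 95)),
    seed = y$seed %||% 1L)
}

#' @rdname read_synthetic_config
#' @param config A [synthetic_config()] to serialise.
#' @export
write_synthetic_config <- function(config, path) {
  y <- list(
    hotspots = if (nrow(config$hotspots)) lapply(
      seq_len(nrow(config$hotspots)),
      function(i) as.list(config$hotspots[i, c("x", "y", "radius", "n")])),
    background_count = config$background_count,
    bounding_box = config$bounding_box,
    beta = as.list(stats::setNames(config$beta, config$beta_names)),
    rho = config$rho,
    covariates = lapply(config$covariates, function(s) {
      if (s$type == "categorical") {
        list(name = s$name, type = "categorical", probs = s$probs)
      } else {
        list(name = s$name, type = "continuous", mean = s$mean, sd = s$sd,
             round_min = s$round_min)
      }
    }),
    weights = config$weights, encoding = config$encoding,
    age_range = config$age_range, seed = config$seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
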