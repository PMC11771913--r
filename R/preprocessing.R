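# Raw crash tables -> analysis-ready binary-outcome dataset: older-driver
# filter, severity binarisation, Pearson collinearity screen, design matrix.

#' Keep only crashes involving older drivers
#'
#' The older-driver convention is age 65 and above; the threshold is
#' inclusive.
#'
#' @param table A crash table with an `age` column (years).
#' @param age_threshold Minimum driver age retained, default 65.
#' @return The filtered crash table (row order preserved).
#' @export
filter_older_drivers <- function(table, age_threshold = 65) {
  if (!"age" %in% names(table)) {
    stop("schema error: crash table has no 'age' column")
  }
  if (any(table$age < 0, na.rm = TRUE)) stop("negative driver ages present")
  out <- table[!is.na(table$age) & table$age >= age_threshold, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(table)
  out
}

#' Binarise crash injury severity
#'
#' Property-damage-only (PDO) crashes become 0; injury and fatality crashes
#' are merged into 1 (fatalities are a fraction of a percent of typical
#' registries, so merging does not materially change the analysis).
#' Already-binary input passes through unchanged. Records with missing
#' severity are dropped with a message; unrecognised codes are an error.
#'
#' @param table A crash table with a `severity` column, either coded
#'   `{"PDO", "injury", "fatality"}` (case-insensitive) or already `{0, 1}`.
#' @return The table with integer `severity` in `{0, 1}`.
#' @export
binarize_severity <- function(table) {
  if (!"severity" %in% names(table)) {
    stop("schema error: crash table has no 'severity' column")
  }
  sev <- table$severity
  na <- is.na(sev)
  if (any(na)) {
    message("dropping ", sum(na), " record(s) with missing severity")
    table <- table[!na, , drop = FALSE]
    sev <- sev[!na]
  }
  if (is.numeric(sev)) {
    bad <- !sev %in% c(0, 1)
    if (any(bad)) {
      stop("unknown numeric severity code(s) in record(s): ",
           paste(utils::head(table$id[bad], 10), collapse = ", "))
    }
    table$severity <- as.integer(sev)
  } else {
    code <- tolower(as.character(sev))
    map <- c(pdo = 0L, injury = 1L, fatality = 1L, "0" = 0L, "1" = 1L)
    bad <- !code %in% names(map)
    if (any(bad)) {
      stop("unknown severity code(s) ",
           paste(unique(sev[bad]), collapse = ", "), " in record(s): ",
           paste(utils::head(table$id[bad], 10), collapse = ", "))
    }
    table$severity <- unname(map[code])
  }
  rownames(table) <- NULL
  table
}

#' Severity shares of a binarised crash table
#'
#' @param table A crash table with binary `severity`.
#' @return Named vector: counts and percentage shares of the PDO (0) and
#'   injury-or-fatality (1) categories.
#' @export
severity_shares <- function(table) {
  sev <- binarize_severity(table)$severity
  n <- length(sev)
  c(n = n, n_pdo = sum(sev == 0), n_injury = sum(sev == 1),
    pct_pdo = 100 * sum(sev == 0) / n, pct_injury = 100 * sum(sev == 1) / n)
}

#' Pearson collinearity screen over candidate predictors
#'
#' Computes all pairwise Pearson correlations and greedily resolves each
#' violating pair (`|r| >= r_threshold`) by dropping the member listed later
#' in `predictors`, repeating until no violation remains. Constant columns
#' cannot enter a correlation and are dropped up front with a warning.
#'
#' @param table Crash table containing the predictor columns.
#' @param predictors Character vector of candidate column names (order
#'   matters: it is the drop tie-break).
#' @param r_threshold Absolute-correlation cutoff, default 0.7.
#' @return List: `retained` (names), `dropped` (names), `report` (data frame
#'   of every flagged pair: `var1`, `var2`, `r`, `dropped`).
#' @export
collinearity_screen <- function(table, predictors, r_threshold = 0.7) {
  stopifnot(length(predictors) >= 2)
  missing <- setdiff(predictors, names(table))
  if (length(missing)) stop("predictor(s) not in table: ",
                            paste(missing, collapse = ", "))
  X <- as.data.frame(table)[predictors]
  report <- data.frame(var1 = character(0), var2 = character(0),
                       r = numeric(0), dropped = character(0))
  const <- vapply(X, function(v) stats::var(v) == 0 || !is.finite(stats::var(v)),
                  logical(1))
  dropped <- character(0)
  if (any(const)) {
    warning("constant column(s) dropped: ",
            paste(predictors[const], collapse = ", "))
    dropped <- predictors[const]
  }
  retained <- setdiff(predictors, dropped)
  repeat {
    if (length(retained) < 2) break
    r <- stats::cor(X[retained])
    diag(r) <- 0
    viol <- which(abs(r) >= r_threshold, arr.ind = TRUE)
    viol <- viol[viol[, 1] < viol[, 2], , drop = FALSE]
    if (nrow(viol) == 0) break
    # resolve the first violating pair (row-major over the retained order);
    # the later-listed member goes
    i <- viol[1, 1]; j <- viol[1, 2]
    drop_var <- retained[max(i, j)]
    report <- rbind(report, data.frame(var1 = retained[i], var2 = retained[j],
                                       r = r[i, j], dropped = drop_var))
    dropped <- c(dropped, drop_var)
    retained <- setdiff(retained, drop_var)
  }
  list(retained = retained, dropped = dropped, report = report)
}

#' Assemble the probit design matrix
#'
#' Prepends an intercept column. Under `"ordinal"` encoding each predictor's
#' integer codes pass through as a single column (one coefficient per
#' variable, the registry-table convention); under `"dummy"` each categorical
#' predictor expands to k-1 indicators against its smallest observed code
#' (the `0`/Unknown base level).
#'
#' @param table A binarised crash table (binary `severity`, `x`/`y` present).
#' @param predictors Character vector of predictor column names.
#' @param encoding `"ordinal"` (default) or `"dummy"`.
#' @return An object of class `design_matrix`: list with `y` (binary
#'   response), `X` (numeric matrix, intercept first), `coords` (n x 2),
#'   `n`, `encoding`.
#' @export
build_design <- function(table, predictors, encoding = c("ordinal", "dummy")) {
  encoding <- match.arg(encoding)
  missing <- setdiff(predictors, names(table))
  if (length(missing)) stop("predictor(s) not in table: ",
                            paste(missing, collapse = ", "))
  if (!all(table$severity %in% c(0, 1))) {
    stop("severity is not binary; run binarize_severity() first")
  }
  if (encoding == "ordinal") {
    X <- cbind("(Intercept)" = 1,
               as.matrix(as.data.frame(table)[predictors]))
  } else {
    pieces <- lapply(predictors, function(p) {
      v <- table[[p]]
      lev <- sort(unique(v))
      if (length(lev) < 2) {
        stop("predictor '", p, "' has a single observed level; ",
             "dummy encoding impossible")
      }
      m <- vapply(lev[-1], function(l) as.numeric(v == l),
                  numeric(nrow(table)))
      colnames(m) <- paste0(p, "_", lev[-1])
      m
    })
    X <- cbind("(Intercept)" = 1, do.call(cbind, pieces))
  }
  structure(list(y = as.integer(table$severity), X = X,
                 coords = as.matrix(as.data.frame(table)[, c("x", "y")]),
                 n = nrow(table), encoding = encoding),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("Design matrix:", x$n, "obs x", ncol(x$X), "columns (",
      x$encoding, "encoding );", sum(x$y), "positive outcomes\n")
  invisible(x)
}
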