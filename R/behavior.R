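#' Cascade count from runs of consecutive catches
#'
#' The behavioral scoring unit is the three-ball cascade (three consecutive
#' catches); each run of consecutive catches contributes
#' \code{floor(run / 3)} cascades, so a run of 2 catches counts nothing.
#'
#' @param runs nonnegative integer vector of consecutive-catch run lengths.
#' @return total cascade count.
#' @export
cascades_from_catch_runs <- function(runs) {
  if (any(!is.finite(runs)) || any(runs < 0) || any(runs != floor(runs)))
    stop("runs must be nonnegative integers")
  sum(runs %/% 3)
}

#' Fit the within-test learning curve
#'
#' Closed-form least-squares line through the block scores of one
#' performance test, with block index x = 1..n:
#' slope m = sum((x - xbar)(y - ybar)) / sum((x - xbar)^2),
#' intercept c = ybar - m * xbar, and task proficiency y1 = m + c, the
#' model-predicted performance at the first block.
#'
#' @param block_scores ordered numeric vector of per-block cascade counts.
#' @return object of class \code{learning_curve} with components \code{m}
#'   (slope, cascades/block), \code{c} (intercept), \code{y1}
#'   (task proficiency), \code{n_blocks} and \code{rss}.
#' @examples
#' fit <- fit_learning_curve(c(4, 9, 11, 17, 21))
#' coef(fit)               # slope, intercept, task proficiency
#' predict(fit, 1:5)
#' @export
fit_learning_curve <- function(block_scores) {
  y <- as.numeric(block_scores)
  n <- length(y)
  if (n < 2) stop("need at least 2 blocks")
  if (any(!is.finite(y))) stop("non-finite block score")
  x <- seq_len(n)
  xb <- mean(x); yb <- mean(y)
  m <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  c0 <- yb - m * xb
  fit <- structure(list(m = m, c = c0, y1 = m + c0, n_blocks = n,
                        rss = sum((y - (c0 + m * x))^2),
                        block_scores = y),
                   class = "learning_curve")
  fit
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf(
    "<learning_curve> m = %.4g cascades/block, c = %.4g, y1 = %.4g (n = %d)\n",
    x$m, x$c, x$y1, x$n_blocks))
  invisible(x)
}

#' @export
coef.learning_curve <- function(object, ...) {
  c(m = object$m, c = object$c, y1 = object$y1)
}

#' @export
predict.learning_curve <- function(object, blocks = seq_len(object$n_blocks),
                                   ...) {
  object$c + object$m * blocks
}

#' Fit learning curves for every subject and performance test in a table
#'
#' @param table behavior data.frame with columns \code{subject},
#'   \code{test}, \code{block}, \code{cascades} (as written by
#'   [generate_cohort()]).
#' @return data.frame (subject, test, m, c, y1, n_blocks).
#' @export
fit_behavior_table <- function(table) {
  stopifnot(all(c("subject", "test", "block", "cascades") %in% names(table)))
  parts <- split(table, list(table$subject, table$test), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(d) {
    d <- d[order(d$block), ]
    f <- fit_learning_curve(d$cascades)
    data.frame(subject = d$subject[1], test = d$test[1],
               m = f$m, c = f$c, y1 = f$y1, n_blocks = f$n_blocks)
  }))
  rownames(out) <- NULL
  out[order(out$subject, out$test), ]
}

#' Overnight change in task proficiency and learning curve
#'
#' Post-minus-pre difference of the fitted y1 and m between two performance
#' tests (default test 2 vs test 1, the retention interval of interest).
#'
#' @param fits data.frame from [fit_behavior_table()].
#' @param pre,post test indices to difference.
#' @return data.frame (subject, delta_y1, delta_m); subjects missing either
#'   test are dropped with a message.
#' @export
overnight_change <- function(fits, pre = 1, post = 2) {
  a <- fits[fits$test == pre, ]
  b <- fits[fits$test == post, ]
  common <- intersect(a$subject, b$subject)
  missing <- setdiff(union(a$subject, b$subject), common)
  if (length(missing))
    message("subjects missing a test, dropped: ",
            paste(missing, collapse = ", "))
  a <- a[match(common, a$subject), ]
  b <- b[match(common, b$subject), ]
  data.frame(subject = common, delta_y1 = b$y1 - a$y1, delta_m = b$m - a$m)
}

#' Rank correlation between fitted proficiency and observed first block
#'
#' Sanity check of the parameterization: the model-predicted first-block
#' performance (y1) should track the observed block-1 cascade count within
#' each performance test.
#'
#' @param fits data.frame from [fit_behavior_table()].
#' @param table the behavior table the fits came from.
#' @return data.frame (test, rho, n).
#' @export
proficiency_vs_first_block <- function(fits, table) {
  tests <- sort(unique(fits$test))
  out <- do.call(rbind, lapply(tests, function(tst) {
    f <- fits[fits$test == tst, ]
    if (nrow(f) < 5) stop("need at least 5 subjects per test")
    b1 <- table[table$test == tst & table$block == 1, ]
    y <- b1$cascades[match(f$subject, b1$subject)]
    if (stats::sd(f$y1) == 0 || stats::sd(y) == 0)
      stop("constant values: rank correlation undefined")
    data.frame(test = tst,
               rho = stats::cor(f$y1, y, method = "spearman"),
               n = nrow(f))
  }))
  rownames(out) <- NULL
  out
}
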