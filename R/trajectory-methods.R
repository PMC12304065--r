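## Methods for moment trajectories (produced by the reduction, by moment
## extraction from a PDE solution, or by the therapy simulator).

#' @export
print.moment_trajectory <- function(x, ...) {
  src <- x$meta$source %||% "unknown"
  cat("Moment trajectory (", src, "): ", ncol(x$m),
      " tracked moment(s), ", length(x$times), " times on [",
      signif(min(x$times), 4), ", ", signif(max(x$times), 4), "]\n", sep = "")
  if (!is.null(x$meta$closure))
    cat(sprintf("  reduction: N = %d, M = %d, closure = %s\n",
                x$meta$N, x$meta$M, x$meta$closure))
  last <- length(x$times)
  cat(sprintf("  final state: P = %.6g, %s\n", x$P[last],
              paste(sprintf("%s = %.6g", colnames(x$m), x$m[last, ]),
                    collapse = ", ")))
  if (!is.null(x$flags) && length(x$flags)) {
    bad <- vapply(x$flags, function(fl) any(!fl), logical(1))
    if (any(bad))
      cat("  flagged invalid:", paste(names(x$flags)[bad], collapse = ", "),
          "\n")
  }
  invisible(x)
}

#' @export
summary.moment_trajectory <- function(object, ...) {
  df <- as.data.frame(object)
  out <- list(range = range(object$times),
              final = df[nrow(df), ],
              P_range = range(object$P),
              meta = object$meta)
  class(out) <- "summary.moment_trajectory"
  out
}

#' @export
print.summary.moment_trajectory <- function(x, ...) {
  cat("Moment trajectory over t in [", x$range[1], ", ", x$range[2], "]\n",
      sep = "")
  cat("  P range: [", signif(x$P_range[1], 6), ", ",
      signif(x$P_range[2], 6), "]\n", sep = "")
  cat("  final state:\n")
  print(x$final, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.moment_trajectory <- function(x, ...) {
  df <- data.frame(t = x$times, P = x$P)
  cbind(df, as.data.frame(x$m))
}

#' @export
plot.moment_trajectory <- function(x, which = NULL, ...) {
  cols <- c("P", colnames(x$m))
  if (!is.null(which)) cols <- intersect(cols, which)
  n <- length(cols)
  op <- graphics::par(mfrow = c(ceiling(n / 2), min(n, 2)),
                      mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  df <- as.data.frame(x)
  for (cn in cols)
    graphics::plot(df$t, df[[cn]], type = "l", xlab = "t", ylab = cn, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a moment trajectory to CSV with a JSON metadata sidecar
#'
#' @param x a `moment_trajectory`.
#' @param file CSV path; metadata goes to `<file>.meta.json`.
#' @return `file`, invisibly.
#' @export
write_moment_trajectory <- function(x, file) {
  df <- as.data.frame(x)
  if (!is.null(x$flags))
    for (nm in names(x$flags)) df[[nm]] <- x$flags[[nm]]
  utils::write.csv(df, file, row.names = FALSE)
  meta <- c(x$meta, list(package_version =
                           as.character(utils::packageVersion("phenomoments"))))
  jsonlite::write_json(meta, paste0(file, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}
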