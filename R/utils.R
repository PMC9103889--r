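# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = "probemap_error", call. = FALSE) {
  msg <- sprintf(fmt, ...)
  cnd <- structure(
    class = c(class, "probemap_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cnd)
}

stop_config <- function(fmt, ...) stopf(fmt, ..., class = "probemap_config_error")
stop_data   <- function(fmt, ...) stopf(fmt, ..., class = "probemap_data_error")

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Coerce points to an n x 3 numeric matrix; non-finite coordinates are an
# invalid-input error everywhere in the package.
as_points <- function(points, allow_empty = TRUE, what = "points") {
  if (is.data.frame(points)) {
    cols <- intersect(c("x", "y", "z"), names(points))
    if (length(cols) == 3L) points <- as.matrix(points[, c("x", "y", "z")])
    else points <- as.matrix(points)
  }
  if (is.null(dim(points))) {
    if (length(points) == 3L) points <- matrix(as.numeric(points), nrow = 1L)
    else if (length(points) == 0L) points <- matrix(numeric(0), ncol = 3L)
    else stop_data("%s must be a 3-vector or an n x 3 matrix", what)
  }
  points <- matrix(as.numeric(points), nrow = nrow(points), ncol = ncol(points),
                   dimnames = dimnames(points))
  if (ncol(points) != 3L) stop_data("%s must have 3 columns (x, y, z)", what)
  if (!allow_empty && nrow(points) == 0L) stop_data("%s must be non-empty", what)
  if (nrow(points) > 0L && any(!is.finite(points)))
    stop_data("%s contain non-finite coordinates", what)
  points
}

check_scalar_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L)
    stop_config("'%s' must be a single number", name)
  if (finite && !is.finite(x)) stop_config("'%s' must be finite", name)
  if (positive && x <= 0) stop_config("'%s' must be > 0 (got %g)", name, x)
  invisible(as.numeric(x))
}
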