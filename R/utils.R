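# internal helpers shared across modules

# clip a numeric vector into [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# stable ln(1 + 10^u), elementwise
log1p10 <- function(u) {
  t <- u * log(10)
  pmax(t, 0) + log1p(exp(-abs(t)))
}

stop_dsskit <- function(msg, class, ...) {
  abort(msg, class = c(class, "dsskit_error"), ...)
}

# check a data frame has the named columns; error names the first missing one
check_columns <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop_dsskit(
      sprintf("%s is missing required column '%s'", what, missing[1]),
      "dsskit_error_missing_column"
    )
  }
  invisible(data)
}

# coerce a partition given as a tibble (item_id, cluster) or a named vector
# into a named character vector of cluster labels
as_partition_vector <- function(p, arg = "partition") {
  if (is.data.frame(p)) {
    check_columns(p, c("item_id", "cluster"), arg)
    out <- setNames(as.character(p$cluster), as.character(p$item_id))
  } else if (!is.null(names(p))) {
    out <- setNames(as.character(p), names(p))
  } else {
    stop_dsskit(
      sprintf("%s must be a tibble with item_id/cluster or a named vector", arg),
      "dsskit_error_bad_partition"
    )
  }
  if (anyDuplicated(names(out)) > 0) {
    stop_dsskit(sprintf("%s assigns some item more than once", arg),
                "dsskit_error_bad_partition")
  }
  out
}
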