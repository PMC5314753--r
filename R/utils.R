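`%||%` <- function(a, b) if (is.null(a)) b else a

AGES <- 0:100

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stop_input("'%s' must be in [%g, %g], got %g", name, lower, upper, x)
  invisible(x)
}

check_proportion <- function(x, name) check_number(x, name, 0, 1)

# Shared validation for the age-indexed tables the whole pipeline exchanges.
check_age_table <- function(x, value_col, name) {
  if (!is.data.frame(x) || !all(c("age", value_col) %in% names(x)))
    stop_input("'%s' must be a data.frame with columns 'age' and '%s'", name, value_col)
  if (!identical(as.integer(x$age), AGES))
    stop_input("'%s' must cover contiguous single-year ages 0-100", name)
  if (any(!is.finite(x[[value_col]])))
    stop_input("'%s' contains non-finite values", name)
  invisible(x)
}

check_aligned <- function(a, b, name_a, name_b) {
  if (!identical(as.integer(a$age), as.integer(b$age)))
    stop_input("'%s' and '%s' must share an identical age support", name_a, name_b)
  invisible(TRUE)
}
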