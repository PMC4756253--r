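# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a sentence template
#'
#' Replaces `{name}` placeholders with the corresponding values of `data`.
#' Unreferenced data entries are ignored; unresolved placeholders are left
#' in place (validate_kb flags templates whose placeholders the engine
#' cannot supply).
#' @noRd
render_template <- function(text, data) {
  for (nm in names(data)) {
    text <- gsub(paste0("{", nm, "}"), data[[nm]], text, fixed = TRUE)
  }
  text
}

#' Format a number for recommendation text: at most one decimal place,
#' integers without a decimal point.
#' @noRd
fmt_num <- function(x) {
  x <- round(as.numeric(x), 1)
  ifelse(abs(x - round(x)) < 1e-9,
         format(round(x), scientific = FALSE, trim = TRUE),
         format(x, nsmall = 1, scientific = FALSE, trim = TRUE))
}

#' Apply a comparison operator by name
#' @noRd
apply_op <- function(x, op, value) {
  switch(op,
    lt = x < value,
    le = x <= value,
    gt = x > value,
    ge = x >= value,
    eq = x == value,
    ne = x != value,
    stop("unknown comparator: ", op, call. = FALSE)
  )
}

#' Safe arithmetic evaluation of a threshold formula over profile fields.
#' Only basic arithmetic and whitelisted field names are allowed, so the
#' knowledge-base file stays data, not code.
#' @noRd
eval_formula <- function(expr_text, facts) {
  expr <- str2lang(expr_text)
  allowed <- c("+", "-", "*", "/", "^", "(", names(facts))
  used <- all.names(expr, unique = TRUE)
  bad <- setdiff(used, allowed)
  if (length(bad) > 0) {
    stop("formula '", expr_text, "' uses disallowed name(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  vals <- Filter(function(v) is.numeric(v), facts)
  eval(expr, envir = vals, enclos = baseenv())
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
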