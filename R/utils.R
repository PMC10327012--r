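# Internal helpers shared across modules.

# Commercial rounding: ties away from zero for positive x (0.5 -> 1).
round_half_up <- function(x) floor(x + 0.5)

# Deterministic 31-bit substream seed derived from a master seed and string
# labels. Used so that, e.g., the wiring draw for one directed type pair does
# not depend on which other pairs exist in the network.
substream_seed <- function(master, ...) {
  s <- paste(c(...), collapse = "\r")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(master) + h) %% 2147483647)
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. `seed = NULL` evaluates `code` unseeded.
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_row <- function(context, row, msg) {
  stop(sprintf("%s, row %s: %s", context, paste(row, collapse = ", "), msg),
       call. = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# CSV reader that round-trips doubles exactly: all columns are read as
# character and converted with base R's correctly rounded parsers, per the
# supplied type map ("c" character, "d" double, "i" integer, "l" logical).
# Columns absent from the file or the map pass through untouched.
read_csv_exact <- function(path, types) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  for (nm in intersect(names(types), names(df))) {
    df[[nm]] <- switch(types[[nm]],
                       c = df[[nm]],
                       d = as.numeric(df[[nm]]),
                       i = as.integer(df[[nm]]),
                       l = as.logical(df[[nm]]))
  }
  df
}

# CSV writer that round-trips doubles exactly: non-integer numeric columns
# are rendered with 17 significant digits before writing.
write_csv_exact <- function(df, path) {
  df <- tibble::as_tibble(df)
  for (col in names(df)) {
    x <- df[[col]]
    if (is.double(x)) {
      out <- sprintf("%.17g", x)
      out[is.na(x)] <- NA_character_
      df[[col]] <- out
    }
  }
  readr::write_csv(df, path, progress = FALSE)
}
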