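# internal helpers shared across modules

# run code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# strand symbols arrive as ASCII "-" or typographic minus; normalize to ASCII
normalize_strand <- function(strand) {
  s <- gsub("−", "-", strand)
  bad <- !s %in% c("+", "-")
  if (any(bad)) {
    stop("invalid strand value(s): ", paste(unique(strand[bad]), collapse = ", "))
  }
  s
}

AS_TYPES <- c("CASSETTE", "MXE", "A5S", "A3S", "IR", "COMPOSITE")

check_as_type <- function(as_type) {
  bad <- !as_type %in% AS_TYPES
  if (any(bad)) {
    stop("unknown alternative-splicing type(s): ",
         paste(unique(as_type[bad]), collapse = ", "))
  }
  as_type
}

# row variances of a matrix ignoring NAs; rows with <2 observations get 0
row_vars <- function(x) {
  n <- rowSums(!is.na(x))
  mu <- rowMeans(x, na.rm = TRUE)
  v <- rowSums((x - mu)^2, na.rm = TRUE) / pmax(n - 1, 1)
  v[n < 2] <- 0
  v[n == 0] <- NA_real_
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a
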