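# Internal helpers shared across modules.

# Round half away from zero (R's round() is banker's rounding).
half_up <- function(x) floor(x + 0.5)

# Evaluate expr with a temporary RNG state when seed is non-NULL;
# the caller's RNG stream is left untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic per-fish seed derived from (root seed, fish id).
# Kept below 2^31 - 1; arithmetic stays exact in double precision.
derive_seed <- function(root_seed, fish_id) {
  id_num <- sum(utf8ToInt(as.character(fish_id)) *
                  seq_along(utf8ToInt(as.character(fish_id))))
  as.integer((as.double(root_seed) * 48271 + id_num * 1009) %% 2147483629)
}

# Least-squares slope of y on x with coefficient of determination.
# Returns slope per unit of x; r_squared is 1 for an exact fit
# (including a constant series, where the residuals are all zero).
ls_slope <- function(x, y) {
  n <- length(x)
  xbar <- mean(x)
  ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  sxy <- sum((x - xbar) * (y - ybar))
  syy <- sum((y - ybar)^2)
  slope <- if (sxx > 0) sxy / sxx else 0
  ss_res <- syy - slope * sxy
  r2 <- if (syy > .Machine$double.eps * n) max(0, min(1, 1 - ss_res / syy)) else 1
  list(slope = slope, r_squared = r2, n = n)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
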