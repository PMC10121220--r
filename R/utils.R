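`%||%` <- function(a, b) if (is.null(a)) b else a

# save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Rotated 2-D Gaussian surface
#'
#' Evaluates the seven-parameter rotated 2-D Gaussian used for receptive
#' field fitting: amplitude `A`, axis standard deviations `B`, `C`
#' (degrees), rotation `D` (radians), center (`E`, `F`) (degrees) and
#' offset `G`.
#'
#' @param x,y Coordinates in degrees.
#' @param p Named vector/list with elements `A`, `B`, `C`, `D`, `E`, `F`, `G`.
#' @return Numeric vector of surface values.
#' @export
gauss2d <- function(x, y, p) {
  u <- (x - p[["E"]]) * cos(p[["D"]]) - (y - p[["F"]]) * sin(p[["D"]])
  v <- (x - p[["E"]]) * sin(p[["D"]]) + (y - p[["F"]]) * cos(p[["D"]])
  p[["A"]] * exp(-u^2 / (2 * p[["B"]]^2) - v^2 / (2 * p[["C"]]^2)) + p[["G"]]
}

# adjusted Rand index between two hard partitions
#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b Integer/factor label vectors of equal length.
#' @return Scalar adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}
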