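# Age x sex grids: the universal carrier for rates, counts, costs and
# utilities. A grid is a 101 x 2 numeric matrix, rows = integer ages 0..100,
# columns = c("male", "female").

#' Ages covered by the model grid
#' @return Integer vector 0 to 100.
#' @export
model_ages <- function() 0:100

#' Sexes covered by the model grid
#' @return Character vector `c("male", "female")`.
#' @export
model_sexes <- function() c("male", "female")

#' Create an age-by-sex grid
#'
#' @param value A scalar, a length-101 vector recycled to both sexes, or a
#'   101 x 2 matrix.
#' @return A 101 x 2 numeric matrix with dimnames `ages` x `sexes`.
#' @export
age_sex_grid <- function(value = 0) {
  ages <- model_ages()
  sexes <- model_sexes()
  if (is.matrix(value)) {
    stopifnot(nrow(value) == length(ages), ncol(value) == length(sexes))
    m <- value
  } else {
    stopifnot(length(value) %in% c(1L, length(ages)))
    m <- matrix(value, nrow = length(ages), ncol = length(sexes))
  }
  dimnames(m) <- list(age = ages, sex = sexes)
  m
}

#' Convert a grid to a long data frame
#'
#' @param grid A 101 x 2 grid from [age_sex_grid()].
#' @param value_name Name for the value column.
#' @return A data frame with columns `age`, `sex` and the value column.
#' @export
grid_to_df <- function(grid, value_name = "value") {
  df <- data.frame(
    age = rep(model_ages(), times = 2L),
    sex = rep(model_sexes(), each = 101L),
    value = c(grid[, "male"], grid[, "female"]),
    stringsAsFactors = FALSE
  )
  names(df)[3L] <- value_name
  df
}

#' Convert a long data frame to a grid
#'
#' @param df Data frame with columns `age`, `sex` and a value column.
#' @param value_name Name of the value column.
#' @return A 101 x 2 grid.
#' @export
grid_from_df <- function(df, value_name = "value") {
  g <- age_sex_grid(NA_real_)
  for (s in model_sexes()) {
    sub <- df[df$sex == s, , drop = FALSE]
    g[match(sub$age, model_ages()), s] <- sub[[value_name]]
  }
  if (anyNA(g)) stop("grid is missing age/sex cells")
  g
}

is_rate_grid <- function(grid, lo = 0, hi = Inf) {
  all(is.finite(grid)) && all(grid >= lo) && all(grid <= hi)
}
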