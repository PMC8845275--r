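#' Construct a life table
#'
#' A background-mortality table of annual death probabilities by age band
#' and sex. Bands must be contiguous and non-overlapping within each sex;
#' any age at or beyond the end of the last band carries probability 1.
#'
#' @param table Data frame with columns `age_from`, `age_to`, `sex`
#'   (`"male"`/`"female"`) and `q` (annual death probability in `[0, 1]`).
#' @return A tibble of class `life_table`.
#' @export
life_table <- function(table) {
  table <- tibble::as_tibble(table)
  need <- c("age_from", "age_to", "sex", "q")
  if (!all(need %in% names(table))) {
    t2d_validation_error("life_table", "needs columns age_from, age_to, sex, q")
  }
  if (any(table$q < 0 | table$q > 1)) {
    t2d_validation_error("q", "probabilities must lie in [0, 1]")
  }
  for (s in unique(table$sex)) {
    rows <- table[table$sex == s, ]
    rows <- rows[order(rows$age_from), ]
    if (any(rows$age_to <= rows$age_from)) {
      t2d_validation_error("age_to", "bands must have positive width")
    }
    if (nrow(rows) > 1 && any(abs(rows$age_from[-1] - rows$age_to[-nrow(rows)]) > 1e-9)) {
      t2d_validation_error("age bands", "must be contiguous and non-overlapping")
    }
  }
  structure(table[order(table$sex, table$age_from), ], class = c("life_table", class(table)))
}

#' Packaged synthetic life table
#'
#' A simplified age-sex life table emulating a Southern-European mortality
#' schedule (five-year bands, 18 to 105 years). Synthetic: shipped so the
#' engine runs out of the box; replace with a national table for applied
#' work.
#'
#' @return A `life_table`.
#' @export
default_life_table <- function() {
  path <- system.file("extdata", "life_table_synthetic.csv", package = "t2dsim", mustWork = TRUE)
  life_table(read.csv(path))
}

# Vectorized annual background mortality lookup. Ages at or beyond the table
# end return 1; ages below the table start are a configuration error.
background_mortality <- function(age, sex, table) {
  q <- numeric(length(age))
  for (s in c("male", "female")) {
    idx <- which(sex == s)
    if (!length(idx)) next
    rows <- table[table$sex == s, ]
    rows <- rows[order(rows$age_from), ]
    if (!nrow(rows)) t2d_config_error(paste0("life table has no rows for sex '", s, "'"))
    a <- age[idx]
    if (any(a < rows$age_from[1])) {
      t2d_config_error(sprintf(
        "age %.1f below life-table start (%.0f)", min(a), rows$age_from[1]
      ))
    }
    band <- findInterval(a, rows$age_from)
    qi <- rows$q[band]
    qi[a >= rows$age_to[nrow(rows)]] <- 1
    q[idx] <- qi
  }
  q
}
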