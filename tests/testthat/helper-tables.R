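# Build small valid trait tables for tests without going through the
# synthetic generator.

REG <- trait_registry()

# n x 34 table with iid uniform values inside each trait's plausible scale
random_table <- function(n, seed = 1, ids = sprintf("T%03d", seq_len(n))) {
  set.seed(seed)
  v <- matrix(runif(n * 34, min = 10, max = 60), n, 34,
              dimnames = list(NULL, REG$code))
  trait_table(v, ids,
              origin = sample(c("YZR", "YER", "NER"), n, replace = TRUE),
              period = sample(c("1953-2000", "2001-2010"), n, replace = TRUE),
              registry = REG)
}

# table from an explicit value matrix (recycled columns allowed)
table_from_values <- function(v, ids = NULL, origin = "YZR",
                              period = "1953-2000") {
  n <- nrow(v)
  if (is.null(ids)) ids <- sprintf("T%03d", seq_len(n))
  trait_table(v, ids, rep_len(origin, n), rep_len(period, n), registry = REG)
}

# write a toy csv with the 3 metadata columns + all 34 traits
toy_csv <- function(path, rows, extra_col = NULL) {
  header <- c("accession_id", "origin", "period", REG$code)
  if (!is.null(extra_col)) header <- c(header, extra_col)
  writeLines(c(paste(header, collapse = ","),
               vapply(rows, paste, character(1), collapse = ",")),
             path)
  path
}

# a full row of 34 numeric trait values as character
toy_row <- function(id, origin = "YZR", period = "1953-2000",
                    values = rep(50, 34)) {
  paste(c(id, origin, period, values), collapse = ",")
}
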