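#' Construct and validate an accession trait table
#'
#' A `trait_table` is the container every stage of the pipeline consumes: an
#' accession-by-trait numeric matrix aligned to the 34-trait registry order,
#' plus two categorical metadata columns (geographic origin and breeding
#' period).
#'
#' Validation is total: any malformed input raises an error and no partially
#' constructed table is returned. Checks: unique accession identifiers, known
#' origin/period levels, all 34 registry traits present, all values finite,
#' and every percentage-scale trait within \[0, 100\].
#'
#' @param values Numeric matrix or data.frame, one row per accession, with
#'   column names covering all registry trait codes (extra columns are
#'   dropped; order is canonicalized to registry order).
#' @param accession_id Character vector of unique accession identifiers.
#' @param origin Character/factor of origins; levels `YZR`, `YER`, `NER`,
#'   `NIR`, `LAN`, `FOR`.
#' @param period Character/factor of breeding periods; levels
#'   `foreign_introduction`, `1953-2000`, `2001-2010`, `2011-2022`.
#' @param registry Trait registry, see [trait_registry()].
#' @return An object of class `trait_table`: a list with elements
#'   `accession_id`, `origin` (factor), `period` (factor), `values`
#'   (numeric matrix with accession ids as rownames, trait codes as
#'   colnames) and `registry`.
#' @seealso [read_trait_table()], [write_trait_table()],
#'   [generate_germplasm()]
#' @export
trait_table <- function(values, accession_id, origin, period,
                        registry = trait_registry()) {
  accession_id <- as.character(accession_id)
  n <- length(accession_id)
  dup <- unique(accession_id[duplicated(accession_id)])
  if (length(dup)) {
    stop("duplicate accession ids: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  origin <- as.character(origin)
  period <- as.character(period)
  bad_o <- setdiff(unique(origin), .origin_levels())
  if (length(bad_o)) {
    stop("unknown origin level(s): ", paste(bad_o, collapse = ", "),
         call. = FALSE)
  }
  bad_p <- setdiff(unique(period), .period_levels())
  if (length(bad_p)) {
    stop("unknown period level(s): ", paste(bad_p, collapse = ", "),
         call. = FALSE)
  }
  if (length(origin) != n || length(period) != n) {
    stop("metadata length does not match number of accessions", call. = FALSE)
  }
  values <- as.matrix(as.data.frame(values, check.names = FALSE))
  missing_tr <- setdiff(registry$code, colnames(values))
  if (length(missing_tr)) {
    stop("missing trait column(s): ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  }
  values <- values[, registry$code, drop = FALSE]
  storage.mode(values) <- "double"
  if (nrow(values) != n) {
    stop("values has ", nrow(values), " rows but ", n, " accession ids",
         call. = FALSE)
  }
  if (n > 0 && !all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite value at accession '", accession_id[bad[1]],
         "', trait '", colnames(values)[bad[2]], "'", call. = FALSE)
  }
  pct <- registry$code[registry$is_percent]
  if (n > 0) {
    v <- values[, pct, drop = FALSE]
    if (any(v < 0 | v > 100)) {
      bad <- which(v < 0 | v > 100, arr.ind = TRUE)[1, ]
      stop("percentage trait out of [0, 100]: accession '",
           accession_id[bad[1]], "', trait '", pct[bad[2]], "'",
           call. = FALSE)
    }
  }
  rownames(values) <- accession_id
  structure(
    list(accession_id = accession_id,
         origin = factor(origin, levels = .origin_levels()),
         period = factor(period, levels = .period_levels()),
         values = values,
         registry = registry),
    class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("Trait table: ", length(x$accession_id), " accessions x ",
      ncol(x$values), " traits\n", sep = "")
  if (length(x$accession_id)) {
    cat("  origins: ",
        paste(sprintf("%s=%d", levels(x$origin), table(x$origin)),
              collapse = " "), "\n", sep = "")
    cat("  periods: ",
        paste(sprintf("%s=%d", levels(x$period), table(x$period)),
              collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.trait_table <- function(x) dim(x$values)

#' @export
as.data.frame.trait_table <- function(x, ...) {
  data.frame(accession_id = x$accession_id,
             origin = as.character(x$origin),
             period = as.character(x$period),
             as.data.frame(x$values, check.names = FALSE),
             check.names = FALSE, row.names = NULL)
}

.detect_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read an accession trait table from CSV/TSV
#'
#' The file must have a header row containing `accession_id`, `origin`,
#' `period` and all 34 registry trait codes, in any column order. Extra
#' columns are ignored with a warning. The delimiter is auto-detected from
#' the file extension (`.tsv`/`.txt` for tab, comma otherwise) and can be
#' overridden.
#'
#' @param path Path to the file.
#' @param registry Trait registry, see [trait_registry()].
#' @param missing_policy `"error"` (default): any missing or non-numeric
#'   cell is an error naming its row and column. `"impute_mean"`: missing
#'   numeric cells are replaced by their column mean and the imputation
#'   count is reported via `message()`.
#' @param delim Optional delimiter override.
#' @return A validated [trait_table()].
#' @export
read_trait_table <- function(path, registry = trait_registry(),
                             missing_policy = c("error", "impute_mean"),
                             delim = NULL) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- .detect_delim(path, delim)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  meta_cols <- c("accession_id", "origin", "period")
  missing_meta <- setdiff(meta_cols, colnames(df))
  if (length(missing_meta)) {
    stop("missing metadata column(s): ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  missing_tr <- setdiff(registry$code, colnames(df))
  if (length(missing_tr)) {
    stop("missing trait column(s): ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(colnames(df), c(meta_cols, registry$code))
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  raw <- df[, registry$code, drop = FALSE]
  vals <- matrix(NA_real_, nrow(raw), ncol(raw),
                 dimnames = list(NULL, colnames(raw)))
  for (j in seq_len(ncol(raw))) {
    cell <- trimws(raw[[j]])
    cell[cell == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad)) {
      stop("non-numeric cell at row ", bad[1], ", trait '",
           colnames(raw)[j], "': '", cell[bad[1]], "'", call. = FALSE)
    }
    vals[, j] <- num
  }
  n_missing <- sum(is.na(vals))
  if (n_missing > 0) {
    if (missing_policy == "error") {
      bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop("missing value at row ", bad[1], ", trait '",
           colnames(vals)[bad[2]], "' (use missing_policy = 'impute_mean' ",
           "to fill with column means)", call. = FALSE)
    }
    for (j in seq_len(ncol(vals))) {
      na_j <- is.na(vals[, j])
      if (any(na_j)) {
        m <- mean(vals[!na_j, j])
        if (!is.finite(m)) {
          stop("cannot impute trait '", colnames(vals)[j],
               "': all values missing", call. = FALSE)
        }
        vals[na_j, j] <- m
      }
    }
    message("imputed ", n_missing, " missing cell(s) with column means")
  }
  trait_table(vals, df$accession_id, df$origin, df$period, registry)
}

#' Write an accession trait table to CSV/TSV
#'
#' Columns are canonicalized to registry order so output files are
#' deterministic. Numeric values are rounded to `precision` decimal places
#' (IEEE round-half-even on the stored doubles), which makes
#' `read_trait_table(write_trait_table(x))` reproduce the numeric payload
#' bit-identically at that precision.
#'
#' @param table A [trait_table()].
#' @param path Output path; delimiter auto-detected from extension unless
#'   `delim` is given.
#' @param precision Decimal places kept (default 6).
#' @param delim Optional delimiter override.
#' @return Invisibly, the path written.
#' @export
write_trait_table <- function(table, path, precision = 6, delim = NULL) {
  stopifnot(inherits(table, "trait_table"))
  delim <- .detect_delim(path, delim)
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  # fixed-notation decimal strings so a write-read-write cycle is
  # byte-stable at the declared precision
  df[num] <- lapply(df[num], function(x) {
    formatC(round(x, precision), format = "f", digits = precision,
            drop0trailing = TRUE)
  })
  ok <- tryCatch({
    utils::write.table(df, path, sep = delim, row.names = FALSE,
                       quote = FALSE)
    TRUE
  }, error = function(e) {
    stop("cannot write trait table to '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}
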