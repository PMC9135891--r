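#' Write a twin cohort to tab-delimited text
#'
#' One row per twin individual, one-line header, empty fields for missing
#' values. A sidecar JSON (`<path>.json`) records the generating
#' configuration, seed and config hash so a cohort file is self-describing.
#'
#' @param cohort A `twin_cohort`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(as.data.frame(cohort), path, na = "")
  cfg <- attr(cohort, "config")
  sidecar <- list(
    seed = attr(cohort, "seed"),
    config_hash = attr(cohort, "config_hash"),
    n_rows = nrow(cohort),
    config = config_to_list(cfg)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

config_to_list <- function(cfg) {
  if (is.null(cfg)) return(NULL)
  out <- unclass(cfg)
  out$traits <- as.data.frame(out$traits)
  out$pgs <- as.data.frame(out$pgs)
  out$RA <- unname(apply(out$RA, 1, as.numeric, simplify = FALSE))
  out$RC <- unname(apply(out$RC, 1, as.numeric, simplify = FALSE))
  out$RE <- unname(apply(out$RE, 1, as.numeric, simplify = FALSE))
  out
}

#' Read a twin cohort written by [write_cohort()]
#'
#' @param path TSV path. If the sidecar JSON is present its seed and config
#'   hash are restored as attributes.
#' @return A tibble of class `twin_cohort`.
#' @export
read_cohort <- function(path) {
  # readr warns before we can inspect problems(); the explicit check below
  # turns any parsing issue into an error with the offending line
  out <- tryCatch(
    suppressWarnings(readr::read_tsv(path, na = "", show_col_types = FALSE,
                                     progress = FALSE)),
    error = function(e) stop("failed to parse cohort file '", path, "': ",
                             conditionMessage(e))
  )
  problems <- readr::problems(out)
  if (nrow(problems)) {
    stop("malformed cohort file '", path, "': parse problem at line ",
         problems$row[1], " (", problems$expected[1], " expected, got ",
         problems$actual[1], ")")
  }
  required <- c("pair_id", "member", "zygosity", "sex")
  absent <- setdiff(required, names(out))
  if (length(absent)) {
    stop("malformed cohort file '", path, "': missing column(s) ",
         paste(absent, collapse = ", "))
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "seed") <- meta$seed
    attr(out, "config_hash") <- meta$config_hash
  }
  class(out) <- c("twin_cohort", class(out))
  out
}
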