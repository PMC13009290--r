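#' Read and write longitudinal weight records
#'
#' Weight records travel as long-format CSV with columns `fish_id`, `pond`,
#' `hapa`, `sex`, `start_weight`, `age`, `weight` (one row per fish and
#' measurement).  Reading validates the invariants: positive weights,
#' strictly increasing ages within fish, and constant covariates per fish.
#'
#' @param path File path.
#' @return `read_weight_records()` returns the validated data frame;
#'   `write_weight_records()` returns `path` invisibly.
#' @export
read_weight_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_weight_records(rec)
}

#' @rdname read_weight_records
#' @param records A weight-record data frame.
#' @export
write_weight_records <- function(records, path) {
  validate_weight_records(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_weight_records
#' @export
validate_weight_records <- function(records) {
  needed <- c("fish_id", "pond", "hapa", "sex", "start_weight", "age", "weight")
  miss <- setdiff(needed, names(records))
  if (length(miss))
    stop("weight records are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(records$weight)) || any(records$weight <= 0))
    stop("all weights must be positive and finite", call. = FALSE)
  if (any(records$age <= 0))
    stop("all ages must be positive", call. = FALSE)
  ord <- order(records$fish_id, records$age)
  rec <- records[ord, , drop = FALSE]
  if (anyDuplicated(paste(rec$fish_id, rec$age)))
    stop("duplicated fish/age records detected", call. = FALSE)
  if (any(unlist(tapply(rec$age, rec$fish_id,
                        function(a) any(diff(a) <= 0)))))
    stop("ages must be strictly increasing within fish", call. = FALSE)
  for (v in c("pond", "hapa", "sex", "start_weight")) {
    if (any(tapply(rec[[v]], rec$fish_id,
                   function(x) length(unique(x))) > 1L))
      stop(sprintf("'%s' must be constant within fish", v), call. = FALSE)
  }
  rownames(rec) <- NULL
  rec
}

# Split long records into a per-fish list of (ages, weights), dropping fish
# with fewer than min_obs retained observations (reported via message).
records_by_fish <- function(records, min_obs = 3L) {
  records <- records[order(records$fish_id, records$age), , drop = FALSE]
  spl <- split(seq_len(nrow(records)), records$fish_id)
  nobs <- lengths(spl)
  dropped <- names(spl)[nobs < min_obs]
  if (length(dropped))
    message(length(dropped), " fish with fewer than ", min_obs,
            " records excluded from growth fitting")
  spl <- spl[nobs >= min_obs]
  lapply(spl, function(i)
    list(ages = records$age[i], weights = records$weight[i],
         rows = i))
}

# One row of per-fish covariates from long records.
fish_covariates <- function(records) {
  first <- !duplicated(records$fish_id)
  out <- records[first, c("fish_id", "pond", "hapa", "sex", "start_weight")]
  rownames(out) <- NULL
  out
}
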