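#' @rdname record_set
#' @export
MODALITIES <- c("MRI", "MEG", "EEG", "MRI+EEG", "MRI+DTI")

#' @rdname record_set
#' @export
INDICATORS <- c("FC", "SC", "gFCD", "lFCD", "EC", "ReHo",
                "network_metric", "unknown")

# indicators that reflect connectivity strength and become network edges
CONNECTIVITY_INDICATORS <- c("FC", "SC", "gFCD", "lFCD", "EC", "ReHo")

#' Literature connectivity-change records
#'
#' A record set holds one row per reported region-pair connectivity change:
#' the study it came from, acquisition modality, the connectivity indicator
#' (FC, SC, gFCD, lFCD, EC, ReHo, a network-model metric, or unknown), the
#' unordered region pair, and either a qualitative direction (+1 increased
#' in patients vs controls, -1 decreased) or a raw correlation coefficient
#' from which the direction is derived. Pairs are canonicalized to
#' lexicographic order; exact duplicate (study, pair, indicator) triples
#' are rejected.
#'
#' @param df data frame with columns `study_id`, `modality`, `indicator`,
#'   `region_a`, `region_b`, `direction`, `raw_r`, `n_patients`,
#'   `n_controls`. Exactly one of `direction`/`raw_r` must be non-missing
#'   per row.
#' @param provenance character tag recording where the rows came from.
#' @param registry optional [region_registry()]; when given, region codes
#'   are normalized against it and unknown codes are an error.
#' @return data frame of class `"record_set"` with attribute `provenance`.
#' @export
record_set <- function(df, provenance = "in-memory", registry = NULL) {
  req <- c("study_id", "modality", "indicator", "region_a", "region_b",
           "direction", "raw_r", "n_patients", "n_controls")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop_jmenet("record set is missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, req]
  df$study_id <- as.character(df$study_id)
  df$region_a <- as.character(df$region_a)
  df$region_b <- as.character(df$region_b)
  df$direction <- suppressWarnings(as.integer(df$direction))
  df$raw_r <- suppressWarnings(as.numeric(df$raw_r))
  df$n_patients <- suppressWarnings(as.integer(df$n_patients))
  df$n_controls <- suppressWarnings(as.integer(df$n_controls))

  bad_mod <- setdiff(unique(df$modality), MODALITIES)
  if (length(bad_mod)) {
    stop_jmenet("unknown modality: %s", paste(bad_mod, collapse = ", "))
  }
  bad_ind <- setdiff(unique(df$indicator), INDICATORS)
  if (length(bad_ind)) {
    stop_jmenet("unknown indicator: %s", paste(bad_ind, collapse = ", "))
  }

  has_dir <- !is.na(df$direction)
  has_r <- !is.na(df$raw_r)
  if (any(has_dir == has_r)) {
    i <- which(has_dir == has_r)[1]
    stop_jmenet(
      "row %d (study %s): exactly one of direction/raw_r must be present",
      i, df$study_id[i])
  }
  if (any(has_dir & !df$direction %in% c(-1L, 1L))) {
    stop_jmenet("direction must be +1 or -1")
  }

  if (!is.null(registry)) {
    df$region_a <- normalize_region(df$region_a, registry)
    df$region_b <- normalize_region(df$region_b, registry)
  }
  if (any(df$region_a == df$region_b)) {
    i <- which(df$region_a == df$region_b)[1]
    stop_jmenet("row %d (study %s): self-pair %s-%s", i, df$study_id[i],
                df$region_a[i], df$region_b[i])
  }
  p <- canonical_pair(df$region_a, df$region_b)
  df$region_a <- p$a
  df$region_b <- p$b

  key <- paste(df$study_id, pair_key(df$region_a, df$region_b),
               df$indicator, sep = "#")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop_jmenet("duplicate (study, pair, indicator) record: %s", dup)
  }

  rownames(df) <- NULL
  attr(df, "provenance") <- provenance
  attr(df, "parsed_at") <- format(Sys.time(), tz = "UTC")
  class(df) <- c("record_set", "data.frame")
  df
}

#' @export
print.record_set <- function(x, ...) {
  cat(sprintf("<record_set> %d records, %d studies, %d region pairs [%s]\n",
              nrow(x), length(unique(x$study_id)),
              length(unique(pair_key(x$region_a, x$region_b))),
              attr(x, "provenance")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Read connectivity-change records from CSV or JSON
#'
#' The CSV header is `study_id,modality,indicator,region_a,region_b,
#' direction,raw_r,n_patients,n_controls` with exactly one of
#' `direction`/`raw_r` blank per row; a JSON array of objects with the same
#' fields is accepted when the file extension is `.json`.
#'
#' @inheritParams record_set
#' @param path file path.
#' @return a [record_set()].
#' @export
read_records <- function(path, registry = NULL) {
  if (!file.exists(path)) stop_jmenet("records file not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    for (col in c("direction", "raw_r", "n_patients", "n_controls")) {
      if (is.null(df[[col]])) df[[col]] <- NA
    }
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  }
  record_set(df, provenance = path, registry = registry)
}

#' Write records to CSV
#' @param records a [record_set()].
#' @param path output path.
#' @export
write_records <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Fisher r-to-z transformation
#'
#' Maps a Pearson correlation r in (-1, 1) to z = 0.5 * log((1+r)/(1-r)).
#' The transform is odd and strictly increasing; |r| >= 1 is outside the
#' domain.
#'
#' @param r numeric vector of correlations, |r| < 1.
#' @param id optional labels used to name offending values in errors.
#' @return numeric vector of z-scores.
#' @examples
#' fisher_r_to_z(c(0, 0.9))
#' @export
fisher_r_to_z <- function(r, id = NULL) {
  r <- as.numeric(r)
  bad <- !is.na(r) & abs(r) >= 1
  if (any(bad)) {
    lab <- if (is.null(id)) which(bad) else id[bad]
    stop_jmenet("fisher_r_to_z: |r| >= 1 for record(s) %s",
                paste(lab, collapse = ", "))
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Qualitative direction of a connectivity change
#'
#' Reduces each record to a signed unit: +1 when connectivity increased in
#' patients relative to controls, -1 when it decreased. Reported directions
#' pass through; raw correlations are Fisher z-transformed and classified by
#' the sign of z. A z of exactly 0 is not classifiable and raises an error.
#' An optional sensitivity threshold `tau` marks records with 0 < |z| < tau
#' as `NA` (sub-threshold; dropped by [sign_records()]).
#'
#' @param records a [record_set()].
#' @param tau nonnegative sensitivity threshold on |z| (default 0).
#' @return integer vector of +1/-1 (or `NA` for sub-threshold records).
#' @export
qualitative_direction <- function(records, tau = 0) {
  stopifnot(tau >= 0)
  out <- records$direction
  from_r <- is.na(out)
  if (any(from_r)) {
    z <- fisher_r_to_z(records$raw_r[from_r],
                       id = paste0(records$study_id[from_r], ":",
                                   records$region_a[from_r], "-",
                                   records$region_b[from_r]))
    if (any(z == 0)) {
      i <- which(from_r)[z == 0][1]
      stop_jmenet(
        "record %s:%s-%s has z = 0 and cannot be classified as increase/decrease",
        records$study_id[i], records$region_a[i], records$region_b[i])
    }
    s <- ifelse(abs(z) < tau, NA_integer_, as.integer(sign(z)))
    out[from_r] <- s
  }
  out
}

#' Fill qualitative directions into a record set
#'
#' Derives `direction` for every raw-correlation record and drops
#' sub-threshold records (|z| < tau) with a logged count.
#'
#' @inheritParams qualitative_direction
#' @return a [record_set()] whose `direction` column is complete (and
#'   `raw_r` cleared). Attribute `n_dropped_subthreshold` counts dropped
#'   rows.
#' @export
sign_records <- function(records, tau = 0) {
  dir <- qualitative_direction(records, tau = tau)
  keep <- !is.na(dir)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(sprintf("sign_records: dropped %d sub-threshold record(s)", n_drop))
  }
  df <- as.data.frame(records)[keep, , drop = FALSE]
  df$direction <- dir[keep]
  df$raw_r <- NA_real_  # direction now carries the classification
  out <- record_set(df, provenance = attr(records, "provenance"))
  attr(out, "n_dropped_subthreshold") <- n_drop
  out
}

#' Apply region-merging conventions
#'
#' Replaces raw region labels by merged registry codes (case-insensitive
#' lookup in `merge_map`, then in the registry itself), drops records whose
#' two endpoints merge into the same code (logged count), and reapplies
#' pair canonicalization. Exact duplicates created by merging are collapsed;
#' a within-study sign contradiction created by merging is an error.
#' Applying the same merge map twice is a no-op.
#'
#' @param records a [record_set()].
#' @param merge_map named character vector, raw label -> registry code.
#' @param registry a [region_registry()].
#' @return merged [record_set()] with attribute `n_dropped_self`.
#' @export
merge_regions <- function(records, merge_map = default_merge_map(),
                          registry = region_registry()) {
  map_one <- function(lab) {
    hit <- match(tolower(lab), tolower(names(merge_map)))
    mapped <- ifelse(is.na(hit), lab, merge_map[hit])
    idx <- match(tolower(mapped), tolower(registry$code))
    if (anyNA(idx)) {
      bad <- unique(lab[is.na(idx)])
      stop_jmenet("merge_regions: unmatched raw label(s): %s",
                  paste(bad, collapse = ", "))
    }
    registry$code[idx]
  }
  df <- as.data.frame(records)
  df$region_a <- map_one(df$region_a)
  df$region_b <- map_one(df$region_b)

  self <- df$region_a == df$region_b
  n_self <- sum(self)
  if (n_self > 0) {
    message(sprintf("merge_regions: dropped %d self-pair record(s)", n_self))
    df <- df[!self, , drop = FALSE]
  }
  p <- canonical_pair(df$region_a, df$region_b)
  df$region_a <- p$a
  df$region_b <- p$b

  key <- paste(df$study_id, pair_key(df$region_a, df$region_b),
               df$indicator, sep = "#")
  dup <- duplicated(key)
  if (any(dup)) {
    # collapse exact duplicates; contradictory signs within a study are an error
    for (k in unique(key[dup])) {
      rows <- df[key == k, ]
      dirs <- unique(rows$direction[!is.na(rows$direction)])
      if (length(dirs) > 1) {
        stop_jmenet("merge_regions: contradictory within-study directions after merge: %s", k)
      }
    }
    df <- df[!dup, , drop = FALSE]
  }

  out <- record_set(df, provenance = attr(records, "provenance"))
  attr(out, "n_dropped_self") <- n_self
  out
}

#' Detect conflicting region pairs
#'
#' A pair conflicts when at least one study reports an increase (+1) and
#' another a decrease (-1) for it.
#'
#' @param records a signed [record_set()] (complete `direction` column).
#' @return data frame with columns `region_a`, `region_b`, `n_increase`,
#'   `n_decrease`, one row per conflicted pair.
#' @export
detect_conflicts <- function(records) {
  dir <- records$direction
  if (anyNA(dir)) stop_jmenet("detect_conflicts: records must be signed first")
  key <- pair_key(records$region_a, records$region_b)
  up <- tapply(dir == 1L, key, sum)
  dn <- tapply(dir == -1L, key, sum)
  conflicted <- names(up)[up > 0 & dn > 0]
  if (!length(conflicted)) {
    return(data.frame(region_a = character(0), region_b = character(0),
                      n_increase = integer(0), n_decrease = integer(0)))
  }
  parts <- strsplit(conflicted, "|", fixed = TRUE)
  data.frame(
    region_a = vapply(parts, `[`, "", 1),
    region_b = vapply(parts, `[`, "", 2),
    n_increase = as.integer(up[conflicted]),
    n_decrease = as.integer(dn[conflicted]),
    stringsAsFactors = FALSE
  )
}

#' Resolve conflicting pairs
#'
#' The default policy removes every record of a conflicted pair (the
#' conservative choice); `"majority"` keeps the majority sign's records and
#' drops the rest (ties drop the whole pair).
#'
#' @param records a signed [record_set()].
#' @param policy `"exclude"` or `"majority"`.
#' @return a [record_set()] with attributes `n_excluded_records` and
#'   `excluded_pairs`.
#' @export
resolve_conflicts <- function(records, policy = c("exclude", "majority")) {
  policy <- match.arg(policy)
  conf <- detect_conflicts(records)
  if (!nrow(conf)) {
    attr(records, "n_excluded_records") <- 0L
    attr(records, "excluded_pairs") <- character(0)
    return(records)
  }
  key <- pair_key(records$region_a, records$region_b)
  conf_key <- pair_key(conf$region_a, conf$region_b)
  drop <- logical(nrow(records))
  fully_excluded <- character(0)
  for (i in seq_len(nrow(conf))) {
    rows <- key == conf_key[i]
    if (policy == "exclude" || conf$n_increase[i] == conf$n_decrease[i]) {
      drop[rows] <- TRUE
      fully_excluded <- c(fully_excluded, conf_key[i])
    } else {
      maj <- if (conf$n_increase[i] > conf$n_decrease[i]) 1L else -1L
      drop[rows & records$direction != maj] <- TRUE
    }
  }
  n_drop <- sum(drop)
  message(sprintf("resolve_conflicts(%s): dropped %d record(s) on %d conflicted pair(s)",
                  policy, n_drop, nrow(conf)))
  out <- record_set(as.data.frame(records)[!drop, , drop = FALSE],
                    provenance = attr(records, "provenance"))
  attr(out, "n_excluded_records") <- n_drop
  attr(out, "excluded_pairs") <- fully_excluded
  out
}

#' Summarize the study corpus
#'
#' Each study contributes its cohort sizes once, however many region-pair
#' records it reports; inconsistent cohort sizes within a study are an
#' error. Modalities are counted per distinct study; indicators per record.
#'
#' @param records a [record_set()].
#' @return list of class `"cohort_summary"`: `n_studies`, `total_patients`,
#'   `total_controls`, `modality_counts`, `indicator_counts`.
#' @export
summarize_cohort <- function(records) {
  if (!nrow(records)) {
    out <- list(n_studies = 0L, total_patients = 0L, total_controls = 0L,
                modality_counts = integer(0), indicator_counts = integer(0))
    class(out) <- "cohort_summary"
    return(out)
  }
  per_study <- unique(as.data.frame(records)[, c("study_id", "n_patients",
                                                 "n_controls")])
  if (anyDuplicated(per_study$study_id)) {
    bad <- unique(per_study$study_id[duplicated(per_study$study_id)])
    stop_jmenet("inconsistent cohort sizes within study: %s",
                paste(bad, collapse = ", "))
  }
  mod <- unique(as.data.frame(records)[, c("study_id", "modality")])
  out <- list(
    n_studies = nrow(per_study),
    total_patients = sum(per_study$n_patients),
    total_controls = sum(per_study$n_controls),
    modality_counts = table(mod$modality),
    indicator_counts = table(records$indicator)
  )
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d studies, %d patients, %d controls\n",
              x$n_studies, x$total_patients, x$total_controls))
  cat("modalities: ",
      paste(names(x$modality_counts), x$modality_counts, sep = "=",
            collapse = ", "), "\n")
  cat("indicators: ",
      paste(names(x$indicator_counts), x$indicator_counts, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}
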