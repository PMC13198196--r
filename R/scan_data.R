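#' Behavior and distance category levels
#'
#' The scan-sampling protocol uses a closed vocabulary of four mutually
#' exclusive behavior categories and three nested distance categories
#' measured in body lengths (BL, ~1 m) from the session's focal animal.
#'
#' @return Character vector of category levels, in canonical order.
#' @export
behavior_levels <- function() c("lying", "standing", "walking", "foraging")

#' @rdname behavior_levels
#' @export
distance_levels <- function() c("within_1BL", "within_3BL", "over_3BL")

#' Construct a scan-sampling dataset
#'
#' A `herd_data` object bundles a roster of individuals (id + sex) with a
#' long-format table of scan records: one row per animal per scan. Each
#' session has a single focal animal; distances and nearest-neighbour ranks
#' are recorded relative to that focal, whose own row carries `NA` for both.
#'
#' @param individuals data.frame with columns `id` (character, unique) and
#'   `sex` (`"female"` or `"male"`).
#' @param scans data.frame with columns `session_id`, `scan_index` (1-4),
#'   `date` (`Date`), `hour` (integer), `focal_id`, `animal_id`, `behavior`
#'   (factor over [behavior_levels()]), `distance_to_focal` (factor over
#'   [distance_levels()], `NA` for the focal), `nn_rank` (integer 1-3 or `NA`).
#' @return An object of class `herd_data`.
#' @export
herd_data <- function(individuals, scans) {
  stopifnot(is.data.frame(individuals), is.data.frame(scans))
  individuals$id <- as.character(individuals$id)
  if (anyDuplicated(individuals$id))
    stop("duplicate individual ids in roster: ",
         paste(unique(individuals$id[duplicated(individuals$id)]), collapse = ", "))
  if (!all(individuals$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male' for every individual")
  need <- c("session_id", "scan_index", "date", "hour", "focal_id",
            "animal_id", "behavior", "distance_to_focal", "nn_rank")
  miss <- setdiff(need, names(scans))
  if (length(miss)) stop("scan table missing columns: ", paste(miss, collapse = ", "))
  scans$session_id <- as.character(scans$session_id)
  scans$scan_index <- as.integer(scans$scan_index)
  scans$focal_id <- as.character(scans$focal_id)
  scans$animal_id <- as.character(scans$animal_id)
  scans$behavior <- factor(as.character(scans$behavior), levels = behavior_levels())
  scans$distance_to_focal <- factor(as.character(scans$distance_to_focal),
                                    levels = distance_levels())
  scans$nn_rank <- as.integer(scans$nn_rank)
  unknown <- setdiff(unique(c(scans$animal_id, scans$focal_id)), individuals$id)
  if (length(unknown))
    stop("scan rows reference ids absent from roster: ",
         paste(unknown, collapse = ", "))
  structure(list(individuals = individuals[, c("id", "sex")], scans = scans),
            class = "herd_data")
}

#' @export
print.herd_data <- function(x, ...) {
  ns <- nrow(unique(x$scans[, c("session_id", "scan_index")]))
  cat("<herd_data> ", nrow(x$individuals), " individuals (",
      sum(x$individuals$sex == "female"), "F/",
      sum(x$individuals$sex == "male"), "M), ",
      length(unique(x$scans$session_id)), " sessions, ",
      ns, " scans, ", nrow(x$scans), " records\n", sep = "")
  invisible(x)
}

#' Read scan-sampling records from CSV
#'
#' Reads a long-format scan table (one row per animal per scan) as exported
#' from field-recording software. Behavior labels are matched
#' case-insensitively against the four-category vocabulary; anything else is
#' a hard error naming the offending rows. Export dialects with different
#' column names are handled through `rename`, a named character vector
#' `c(canonical = "export_name")`.
#'
#' @param path CSV file with header; required columns `session_id`,
#'   `scan_index`, `timestamp` (`"YYYY-mm-dd HH:MM"`), `focal_id`,
#'   `animal_id`, `behavior`, `distance_to_focal`, `nn_rank`, and `sex`
#'   unless `roster` is supplied.
#' @param roster optional data.frame (`id`, `sex`) used instead of a per-row
#'   `sex` column; per-row sex columns risk contradictory rows, so a roster
#'   is preferred.
#' @param rename optional named character vector mapping canonical column
#'   names to the names used in the file.
#' @return A [herd_data] object. Timestamps are kept to minute resolution;
#'   the integer hour is extracted for later use as a random effect.
#' @export
read_scans <- function(path, roster = NULL, rename = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(rename)) {
    for (canon in names(rename)) {
      j <- match(rename[[canon]], names(raw))
      if (!is.na(j)) names(raw)[j] <- canon
    }
  }
  need <- c("session_id", "scan_index", "timestamp", "focal_id", "animal_id",
            "behavior", "distance_to_focal", "nn_rank")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("input is missing columns: ", paste(miss, collapse = ", "))

  ts <- as.POSIXct(raw$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M"))
  if (anyNA(ts)) stop("unparseable timestamps at rows: ",
                      paste(utils::head(which(is.na(ts)), 5), collapse = ", "))

  beh <- tolower(trimws(raw$behavior))
  beh[beh == ""] <- NA_character_
  bad <- which(!is.na(beh) & !beh %in% behavior_levels())
  if (length(bad))
    stop("unknown behavior label(s) ", paste(unique(beh[bad]), collapse = ", "),
         " at rows ", paste(utils::head(bad, 5), collapse = ", "),
         "; accepted labels: ", paste(behavior_levels(), collapse = ", "))

  dst <- trimws(as.character(raw$distance_to_focal))
  dst[dst == "" | is.na(dst)] <- NA_character_
  badd <- which(!is.na(dst) & !dst %in% distance_levels())
  if (length(badd))
    stop("unknown distance category at rows ",
         paste(utils::head(badd, 5), collapse = ", "),
         "; accepted: ", paste(distance_levels(), collapse = ", "))

  nn <- suppressWarnings(as.integer(raw$nn_rank))
  badn <- which(!is.na(nn) & (nn < 1L | nn > 3L))
  if (length(badn))
    stop("nn_rank outside 1-3 at rows ", paste(utils::head(badn, 5), collapse = ", "))

  key <- paste(raw$session_id, raw$scan_index, raw$animal_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- raw[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate record for animal '", d$animal_id, "' in scan (",
         d$session_id, ", ", d$scan_index, ")")
  }

  if (is.null(roster)) {
    if (!"sex" %in% names(raw))
      stop("no 'sex' column and no roster supplied")
    sx <- tolower(trimws(raw$sex))
    roster <- unique(data.frame(id = as.character(raw$animal_id), sex = sx,
                                stringsAsFactors = FALSE))
    if (anyDuplicated(roster$id))
      stop("contradictory sex entries for id(s): ",
           paste(unique(roster$id[duplicated(roster$id)]), collapse = ", "))
  } else {
    roster <- data.frame(id = as.character(roster$id),
                         sex = tolower(as.character(roster$sex)),
                         stringsAsFactors = FALSE)
  }

  scans <- data.frame(
    session_id = as.character(raw$session_id),
    scan_index = as.integer(raw$scan_index),
    date = as.Date(ts),
    hour = as.integer(format(ts, "%H")),
    focal_id = as.character(raw$focal_id),
    animal_id = as.character(raw$animal_id),
    behavior = beh,
    distance_to_focal = dst,
    nn_rank = nn,
    stringsAsFactors = FALSE
  )
  herd_data(roster, scans)
}

#' Write a scan dataset back to CSV
#'
#' Inverse of [read_scans()]: rows and values round-trip exactly.
#'
#' @param x a [herd_data] object.
#' @param path output CSV path.
#' @export
write_scans <- function(x, path) {
  s <- x$scans
  out <- data.frame(
    session_id = s$session_id,
    scan_index = s$scan_index,
    timestamp = sprintf("%s %02d:%02d", format(s$date), s$hour,
                        5L * (s$scan_index - 1L)),
    focal_id = s$focal_id,
    animal_id = s$animal_id,
    sex = x$individuals$sex[match(s$animal_id, x$individuals$id)],
    behavior = as.character(s$behavior),
    distance_to_focal = as.character(s$distance_to_focal),
    nn_rank = s$nn_rank,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a scan dataset
#'
#' Reports per-scan violations of the scan-sampling invariants without
#' raising errors: a scan whose focal animal has no row (`missing_focal`),
#' duplicated nearest-neighbour ranks (`duplicate_nn`), a focal row carrying
#' a distance or neighbour rank (`focal_nonnull_distance`), and rows with an
#' unrecorded behavior (`incomplete_behavior`).
#'
#' @param x a [herd_data] object.
#' @return list with elements `ok` (logical all-clear flag) and `violations`
#'   (data.frame: `session_id`, `scan_index`, `kind`, `detail`).
#' @export
validate_scans <- function(x) {
  s <- x$scans
  keys <- unique(s[, c("session_id", "scan_index")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    rows <- s[s$session_id == keys$session_id[i] & s$scan_index == keys$scan_index[i], ]
    add <- function(kind, detail)
      out[[length(out) + 1L]] <<- data.frame(
        session_id = keys$session_id[i], scan_index = keys$scan_index[i],
        kind = kind, detail = detail, stringsAsFactors = FALSE)
    focal <- rows$focal_id[1]
    frow <- rows[rows$animal_id == focal, , drop = FALSE]
    if (nrow(frow) == 0L) add("missing_focal", focal)
    else if (!is.na(frow$distance_to_focal[1]) || !is.na(frow$nn_rank[1]))
      add("focal_nonnull_distance", focal)
    nn <- rows$nn_rank[!is.na(rows$nn_rank)]
    if (anyDuplicated(nn))
      add("duplicate_nn", paste(sort(nn[duplicated(nn)]), collapse = ","))
    if (anyNA(rows$behavior))
      add("incomplete_behavior",
          paste(rows$animal_id[is.na(rows$behavior)], collapse = ","))
  }
  violations <- if (length(out)) do.call(rbind, out) else
    data.frame(session_id = character(), scan_index = integer(),
               kind = character(), detail = character(), stringsAsFactors = FALSE)
  list(ok = nrow(violations) == 0L, violations = violations)
}

#' Drop sessions containing incomplete scans
#'
#' Sessions in which any present animal's behavior went unrecorded are
#' removed whole, mirroring the field protocol's discard of sessions missing
#' the behavior of group members.
#'
#' @param x a [herd_data] object.
#' @return A [herd_data] object restricted to complete sessions.
#' @export
drop_incomplete_sessions <- function(x) {
  bad <- unique(x$scans$session_id[is.na(x$scans$behavior)])
  if (length(bad))
    message("dropping ", length(bad), " session(s) with unrecorded behaviors")
  x$scans <- x$scans[!x$scans$session_id %in% bad, , drop = FALSE]
  x
}

scan_keys <- function(x) unique(x$scans[, c("session_id", "scan_index")])

#' Group size per scan
#'
#' Group size is the number of distinct animals recorded in a scan, focal
#' included.
#'
#' @param x a [herd_data] object with at least one scan.
#' @return list with `mean`, `min`, `max`, `sd`, `n_scans`, and `sizes`
#'   (integer vector, one entry per scan).
#' @export
group_size_summary <- function(x) {
  if (nrow(x$scans) == 0L) stop("dataset contains no scans")
  key <- paste(x$scans$session_id, x$scans$scan_index, sep = "\r")
  sizes <- as.integer(tapply(x$scans$animal_id, key,
                             function(a) length(unique(a))))
  list(mean = mean(sizes), min = min(sizes), max = max(sizes),
       sd = stats::sd(sizes), n_scans = length(sizes), sizes = sizes)
}

#' Per-individual activity budget
#'
#' For each individual, the proportion of its scan records spent in each of
#' the four behavior categories (e.g. foraging proportion = scans observed
#' foraging / total scans observed). Rows sum to 1. Roster individuals never
#' observed are excluded with a warning.
#'
#' @param x a [herd_data] object.
#' @return data.frame with columns `id`, `sex`, `n_obs` and one proportion
#'   column per behavior level.
#' @export
behavior_budget <- function(x) {
  s <- x$scans[!is.na(x$scans$behavior), ]
  tab <- table(s$animal_id, s$behavior)
  n <- rowSums(tab)
  zero <- setdiff(x$individuals$id, rownames(tab)[n > 0])
  if (length(zero))
    warning("individual(s) with zero observations excluded from budget: ",
            paste(zero, collapse = ", "))
  tab <- tab[n > 0, , drop = FALSE]
  props <- sweep(unclass(tab), 1, rowSums(tab), "/")
  out <- data.frame(id = rownames(tab),
                    sex = x$individuals$sex[match(rownames(tab), x$individuals$id)],
                    n_obs = as.integer(rowSums(tab)),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(props[, behavior_levels(), drop = FALSE]))
  rownames(out) <- NULL
  out
}
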