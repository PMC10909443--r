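#' Study design for a translocation mark--recapture survey
#'
#' A study design bundles everything about the survey layout that is not an
#' individual capture history: the number of occasions, their timing in
#' months since the release, the first occasion at which wild-born recruits
#' can appear (`tau`), the number of translocated individuals (`n0`), the
#' total number of observed individuals (`D`), optional group labels and an
#' optional table of per-occasion covariates.
#'
#' Occasions are 1-based and occasion 1 is the release: every translocated
#' individual is recorded there with probability 1. Wild-born individuals
#' can first be detected at occasion `tau` or later.
#'
#' @param n_occasions number of survey occasions `T` (release included).
#' @param occasion_times elapsed months from the release for each occasion;
#'   strictly increasing with `occasion_times[1] == 0`. Defaults to
#'   `0:(T-1)` (monthly surveys).
#' @param tau first occasion at which new (wild-born) entrants can be
#'   detected; must satisfy `2 <= tau <= T`.
#' @param n0 number of translocated individuals.
#' @param D number of observed individuals, translocated included.
#' @param groups character vector of group labels in use (may be empty).
#' @param covariates optional data frame of per-occasion covariates with
#'   `n_occasions` rows (e.g. columns `effort`, `airtemp`, `moon`).
#' @return an object of class `tjs_design`.
#' @export
tjs_design <- function(n_occasions, occasion_times = NULL, tau = 2,
                       n0 = 0L, D = 0L, groups = character(),
                       covariates = NULL) {
  T <- as.integer(n_occasions)
  if (is.na(T) || T < 2)
    stop("a design needs at least 2 occasions")
  if (is.null(occasion_times)) occasion_times <- as.numeric(0:(T - 1))
  occasion_times <- as.numeric(occasion_times)
  if (length(occasion_times) != T)
    stop("occasion_times must have one entry per occasion")
  if (occasion_times[1] != 0)
    stop("occasion_times must start at 0 (the release)")
  if (any(diff(occasion_times) <= 0))
    stop("occasion_times must be strictly increasing")
  tau <- as.integer(tau)
  if (tau < 2 || tau > T)
    stop("tau must satisfy 2 <= tau <= T")
  if (n0 > D)
    stop("n0 cannot exceed D")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != T)
      stop("covariates must have one row per occasion")
  }
  structure(
    list(T = T, occasion_times = occasion_times,
         intervals = diff(occasion_times), tau = tau,
         n0 = as.integer(n0), D = as.integer(D),
         groups = as.character(groups), covariates = covariates),
    class = "tjs_design")
}

#' @export
print.tjs_design <- function(x, ...) {
  cat("Translocation JS study design\n")
  cat(sprintf("  occasions: %d (months %s)\n", x$T,
              paste(format(x$occasion_times, trim = TRUE), collapse = ", ")))
  cat(sprintf("  tau (first wild entry occasion): %d\n", x$tau))
  cat(sprintf("  individuals: D = %d observed, n0 = %d translocated\n",
              x$D, x$n0))
  if (length(x$groups))
    cat(sprintf("  groups: %s\n", paste(x$groups, collapse = ", ")))
  if (!is.null(x$covariates))
    cat(sprintf("  occasion covariates: %s\n",
                paste(names(x$covariates), collapse = ", ")))
  invisible(x)
}

occ_cols <- function(T) paste0("occ", seq_len(T))

#' Assemble a capture-history table
#'
#' Histories are stored as a plain data frame with one row per observed
#' individual: columns `id`, `origin` (`"translocated"` or `"wild"`),
#' `group` (label or `NA`) and `occ1 .. occT` holding the binary detection
#' vector. Never-detected individuals are never materialised as rows; they
#' enter the likelihood only through the never-seen history probability.
#'
#' @param detections numeric/integer matrix (individuals x occasions) of 0/1.
#' @param origin character vector, `"translocated"` or `"wild"`.
#' @param id individual identifiers; generated if missing.
#' @param group optional group labels.
#' @return data frame of capture histories.
#' @export
tjs_histories <- function(detections, origin, id = NULL, group = NULL) {
  detections <- as.matrix(detections)
  n <- nrow(detections)
  if (is.null(id)) id <- sprintf("ind%04d", seq_len(n))
  if (is.null(group)) group <- rep(NA_character_, n)
  origin <- match.arg(as.character(origin), c("translocated", "wild"),
                      several.ok = TRUE)
  if (length(origin) == 1) origin <- rep(origin, n)
  df <- data.frame(id = as.character(id), origin = origin,
                   group = as.character(group),
                   stringsAsFactors = FALSE)
  det <- as.data.frame(detections)
  names(det) <- occ_cols(ncol(detections))
  cbind(df, det)
}

#' Extract the detection matrix from a history table
#' @param histories capture-history data frame.
#' @return integer matrix, individuals x occasions.
#' @export
detection_matrix <- function(histories) {
  cols <- grep("^occ[0-9]+$", names(histories), value = TRUE)
  m <- as.matrix(histories[, cols, drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

#' First and last capture occasions
#'
#' `f_i` is the occasion of first capture, `delta_i` the occasion of last
#' capture; both are derived from the stored detection vector.
#' @param histories capture-history data frame.
#' @return integer vector of occasions.
#' @export
first_capture <- function(histories) {
  m <- detection_matrix(histories)
  apply(m, 1, function(r) which(r == 1)[1])
}

#' @rdname first_capture
#' @export
last_capture <- function(histories) {
  m <- detection_matrix(histories)
  apply(m, 1, function(r) max(which(r == 1)))
}

#' Validate a design/history pair
#'
#' Checks the structural invariants: detection vectors have length `T`,
#' every stored history has at least one detection, translocated
#' individuals are detected at the release (occasion 1), wild individuals
#' carry no detections before `tau`, and the design's `D`/`n0` counts agree
#' with the table.
#'
#' @param design a `tjs_design`.
#' @param histories capture-history data frame.
#' @return the (invisibly returned) histories, or an error.
#' @export
validate_data <- function(design, histories) {
  m <- detection_matrix(histories)
  if (ncol(m) != design$T)
    stop(sprintf("history length %d does not match design T = %d",
                 ncol(m), design$T))
  if (!all(m %in% c(0L, 1L)))
    stop("detections must be 0/1")
  rows <- rowSums(m)
  if (any(rows == 0))
    stop(sprintf("history with no detections at row %d (never-seen individuals are not stored)",
                 which(rows == 0)[1]))
  tr <- histories$origin == "translocated"
  if (any(tr & m[, 1] != 1L))
    stop(sprintf("translocated history not detected at release (row %d)",
                 which(tr & m[, 1] != 1L)[1]))
  if (design$tau > 1) {
    pre <- m[, seq_len(design$tau - 1), drop = FALSE]
    bad <- !tr & rowSums(pre) > 0
    if (any(bad))
      stop(sprintf("wild history with detection before tau = %d (row %d)",
                   design$tau, which(bad)[1]))
  }
  if (design$D != nrow(histories))
    stop(sprintf("design D = %d but %d histories attached",
                 design$D, nrow(histories)))
  if (design$n0 != sum(tr))
    stop(sprintf("design n0 = %d but %d translocated histories attached",
                 design$n0, sum(tr)))
  invisible(histories)
}

derive_design_counts <- function(design, histories) {
  design$D <- nrow(histories)
  design$n0 <- sum(histories$origin == "translocated")
  g <- unique(histories$group)
  design$groups <- sort(g[!is.na(g)])
  design
}

#' Read capture histories from file
#'
#' Two dialects are supported. `"csv"` has header
#' `id,origin,group,occ1..occT`, one row per individual, detections
#' strictly `0`/`1`. `"inp"` is the program-MARK style
#' `<binary history> <freq_translocated> <freq_wild>;` with one record per
#' line and `/* ... */` comments ignored; origin is carried by the two
#' frequency columns and individual ids/group labels are not represented.
#'
#' The survey layout (occasion times, `tau`) can be supplied through a
#' key-value design file (see [read_design()]); otherwise `tau` defaults to
#' the earliest first-capture occasion among wild individuals (or 2 when
#' none are present) and occasion times to monthly spacing.
#'
#' @param path file to read.
#' @param dialect `"csv"` or `"inp"`.
#' @param design_path optional design file.
#' @param tau override for `tau` when no design file is given.
#' @return `list(design = <tjs_design>, histories = <data frame>)`.
#' @export
read_histories <- function(path, dialect = c("csv", "inp"),
                           design_path = NULL, tau = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  histories <- switch(dialect,
                      csv = read_histories_csv(path),
                      inp = read_histories_inp(path))
  T <- ncol(detection_matrix(histories))
  if (!is.null(design_path)) {
    design <- read_design(design_path)
    if (design$T != T)
      stop(sprintf("design file T = %d does not match data T = %d",
                   design$T, T))
  } else {
    if (is.null(tau)) {
      fw <- first_capture(histories)[histories$origin == "wild"]
      tau <- if (length(fw)) min(fw) else 2L
    }
    design <- tjs_design(T, tau = tau)
  }
  design <- derive_design_counts(design, histories)
  validate_data(design, histories)
  list(design = design, histories = histories)
}

read_histories_csv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("CSV file has no data rows")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  T <- length(header) - 3L
  if (T < 1 || !identical(header[1:3], c("id", "origin", "group")) ||
      !identical(header[-(1:3)], occ_cols(T)))
    stop("CSV header must be id,origin,group,occ1..occT")
  rows <- strsplit(lines[-1], ",", fixed = TRUE)
  parse_row <- function(i) {
    fields <- rows[[i]]
    if (length(fields) != T + 3L)
      stop(sprintf("parse error at line %d: expected %d fields, found %d",
                   i + 1L, T + 3L, length(fields)))
    det <- fields[-(1:3)]
    if (!all(det %in% c("0", "1")))
      stop(sprintf("parse error at line %d: detections must be 0/1", i + 1L))
    if (!fields[2] %in% c("translocated", "wild"))
      stop(sprintf("parse error at line %d: origin must be translocated/wild",
                   i + 1L))
    c(fields[1:3], det)
  }
  parsed <- t(vapply(seq_along(rows), parse_row, character(T + 3L)))
  grp <- parsed[, 3]
  grp[grp == ""] <- NA_character_
  det <- matrix(as.integer(parsed[, -(1:3)]), ncol = T)
  tjs_histories(det, origin = parsed[, 2], id = parsed[, 1], group = grp)
}

read_histories_inp <- function(path) {
  txt <- paste(readLines(path), collapse = "\n")
  txt <- gsub("/\\*.*?\\*/", " ", txt)          # strip comments
  recs <- strsplit(txt, ";", fixed = TRUE)[[1]]
  recs <- trimws(recs)
  recs <- recs[nzchar(recs)]
  if (!length(recs)) stop("INP file contains no records")
  det_list <- list(); origin <- character(0)
  for (k in seq_along(recs)) {
    tok <- strsplit(recs[k], "[[:space:]]+")[[1]]
    if (length(tok) != 3 || !grepl("^[01]+$", tok[1]) ||
        anyNA(suppressWarnings(as.integer(tok[2:3]))))
      stop(sprintf("parse error in INP record %d: '%s'", k, recs[k]))
    h <- as.integer(strsplit(tok[1], "")[[1]])
    ft <- as.integer(tok[2]); fw <- as.integer(tok[3])
    if (ft > 0) { det_list <- c(det_list, rep(list(h), ft))
                  origin <- c(origin, rep("translocated", ft)) }
    if (fw > 0) { det_list <- c(det_list, rep(list(h), fw))
                  origin <- c(origin, rep("wild", fw)) }
  }
  Ts <- lengths(det_list)
  if (length(unique(Ts)) != 1)
    stop("INP records have inconsistent history lengths")
  tjs_histories(do.call(rbind, det_list), origin = origin)
}

#' Write capture histories to file
#'
#' Round-trips with [read_histories()]: the CSV dialect preserves ids,
#' origin and group labels exactly; the INP dialect aggregates identical
#' (history, origin) records into frequency counts and therefore preserves
#' histories as a multiset but not ids or group labels.
#'
#' @param design a `tjs_design`.
#' @param histories capture-history data frame.
#' @param path output file.
#' @param dialect `"csv"` or `"inp"`.
#' @return `path`, invisibly.
#' @export
write_histories <- function(design, histories, path,
                            dialect = c("csv", "inp")) {
  dialect <- match.arg(dialect)
  validate_data(design, histories)
  m <- detection_matrix(histories)
  if (dialect == "csv") {
    grp <- histories$group
    grp[is.na(grp)] <- ""
    lines <- c(paste(c("id", "origin", "group", occ_cols(design$T)),
                     collapse = ","),
               vapply(seq_len(nrow(m)), function(i)
                 paste(c(histories$id[i], histories$origin[i], grp[i],
                         m[i, ]), collapse = ","), character(1)))
  } else {
    key <- apply(m, 1, paste, collapse = "")
    tab <- table(key, factor(histories$origin,
                             c("translocated", "wild")))
    lines <- sprintf("%s %d %d;", rownames(tab), tab[, 1], tab[, 2])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write survey design files
#'
#' Plain key-value text: lines `T: 10`, `tau: 4`,
#' `occasion_times_months: 0,6,12,...` and optional per-occasion covariate
#' columns `cov_<name>: v1,v2,...` with one value per occasion.
#'
#' @param path design file.
#' @return a `tjs_design` (with `D`/`n0` zero until data are attached).
#' @export
read_design <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^:]+):(.*)$", lines))
  if (any(lengths(kv) != 3))
    stop("malformed design file line: ", lines[which(lengths(kv) != 3)[1]])
  keys <- trimws(vapply(kv, `[`, character(1), 2))
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  get <- function(k) vals[match(k, keys)]
  T <- as.integer(get("T"))
  times <- if (!is.na(get("occasion_times_months")))
    as.numeric(strsplit(get("occasion_times_months"), ",")[[1]]) else NULL
  tau <- if (!is.na(get("tau"))) as.integer(get("tau")) else 2L
  covs <- NULL
  ck <- grep("^cov_", keys)
  if (length(ck)) {
    covs <- as.data.frame(lapply(vals[ck], function(v)
      as.numeric(strsplit(v, ",")[[1]])))
    names(covs) <- sub("^cov_", "", keys[ck])
  }
  tjs_design(T, occasion_times = times, tau = tau, covariates = covs)
}

#' @rdname read_design
#' @param design a `tjs_design` to serialise.
#' @export
write_design <- function(design, path) {
  lines <- c(sprintf("T: %d", design$T),
             sprintf("tau: %d", design$tau),
             sprintf("occasion_times_months: %s",
                     paste(format(design$occasion_times, trim = TRUE),
                           collapse = ",")))
  if (!is.null(design$covariates))
    lines <- c(lines, vapply(names(design$covariates), function(nm)
      sprintf("cov_%s: %s", nm,
              paste(format(design$covariates[[nm]], trim = TRUE),
                    collapse = ",")), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Per-occasion summary of a capture-history dataset
#'
#' @param design a `tjs_design`.
#' @param histories capture-history data frame.
#' @return list with per-occasion capture counts, first-capture counts and
#'   interval lengths (months); first-capture counts sum to `D`.
#' @export
summarize_histories <- function(design, histories) {
  validate_data(design, histories)
  m <- detection_matrix(histories)
  f <- first_capture(histories)
  list(captures = colSums(m),
       first_captures = tabulate(f, nbins = design$T),
       intervals = design$intervals,
       D = design$D, n0 = design$n0)
}
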