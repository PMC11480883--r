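#' Read a per-residue relaxation table from CSV/TSV
#'
#' Canonical columns are `residue`, `resname`, `field_MHz`, `R2`, `R2_err`,
#' `R1`, `hetNOE`, `region`; only `residue` and `R2` are required. Other
#' column names can be mapped via `column_map`. The magnetic field may be
#' given per row (`field_MHz` column) or once via `field_mhz`. Rows with
#' missing or non-positive R2 are skipped with a warning, never imputed.
#'
#' @param path file path (CSV, or TSV when `sep = "\t"`).
#' @param column_map named character vector mapping canonical names to the
#'   file's column names, e.g. `c(residue = "resid", R2 = "R2_500")`.
#' @param field_mhz proton frequency in MHz applied to all rows lacking one.
#' @param sep field separator (default `,`).
#' @return data.frame of records with the canonical columns; number of
#'   skipped rows in attribute `"n_skipped"`.
#' @export
read_relaxation_csv <- function(path, column_map = NULL, field_mhz = NULL,
                                sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  canon <- c("residue", "resname", "field_MHz", "R2", "R2_err", "R1",
             "hetNOE", "region")
  for (nm in names(column_map)) {
    if (!column_map[[nm]] %in% names(df))
      stop(sprintf("column_map names missing column '%s' in %s",
                   column_map[[nm]], path), call. = FALSE)
    names(df)[names(df) == column_map[[nm]]] <- nm
  }
  for (req in c("residue", "R2")) {
    if (!req %in% names(df))
      stop(sprintf("required column '%s' not found in %s (have: %s)",
                   req, path, paste(names(df), collapse = ", ")), call. = FALSE)
  }
  if (!"field_MHz" %in% names(df)) {
    if (is.null(field_mhz))
      stop("no field_MHz column and no `field_mhz` given; the magnetic field is required",
           call. = FALSE)
    df$field_MHz <- field_mhz
  }
  for (nm in setdiff(canon, names(df))) df[[nm]] <- NA
  df <- df[canon]
  df$residue <- as.integer(df$residue)
  for (nm in c("field_MHz", "R2", "R2_err", "R1", "hetNOE"))
    df[[nm]] <- suppressWarnings(as.numeric(df[[nm]]))
  bad <- is.na(df$R2) | df$R2 <= 0
  if (any(bad)) {
    warning(sprintf("%d row(s) with missing or non-positive R2 skipped in %s",
                    sum(bad), basename(path)), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "n_skipped") <- sum(bad)
  df
}

#' Write a per-residue relaxation table
#'
#' Inverse of [read_relaxation_csv()]; numeric fields keep full precision
#' (15 significant digits) so a read/write round trip is lossless at 12
#' significant digits.
#'
#' @param records data.frame of records.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_relaxation_csv <- function(records, path, sep = ",") {
  out <- records
  for (nm in names(out))
    if (is.numeric(out[[nm]])) out[[nm]] <- formatC(out[[nm]], digits = 15,
                                                    format = "g")
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- minimal NMR-STAR 3.1 reading (heteronuclear T2/R2 save-frames) -------

# split a STAR data line into tokens, honouring single/double quotes
star_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  if (m[1] == -1) return(character(0))
  tok <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", tok)
}

parse_star_saveframes <- function(lines) {
  lines <- sub("#.*$", "", lines)
  frames <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[i])
    if (grepl("^save_.+", ln)) {
      frame <- list(name = sub("^save_", "", ln), tags = list(), loops = list())
      i <- i + 1L
      while (i <= n && trimws(lines[i]) != "save_") {
        ln2 <- trimws(lines[i])
        if (ln2 == "" ) { i <- i + 1L; next }
        if (grepl("^_", ln2)) {
          tok <- star_tokens(ln2)
          frame$tags[[tok[1]]] <- if (length(tok) >= 2) paste(tok[-1], collapse = " ") else NA
          i <- i + 1L
        } else if (ln2 == "loop_") {
          i <- i + 1L
          cols <- character(0)
          while (i <= n && grepl("^_", trimws(lines[i]))) {
            cols <- c(cols, star_tokens(trimws(lines[i]))[1])
            i <- i + 1L
          }
          rows <- list()
          while (i <= n && !trimws(lines[i]) %in% c("stop_", "save_")) {
            ln3 <- trimws(lines[i])
            if (ln3 != "") rows[[length(rows) + 1L]] <- star_tokens(ln3)
            i <- i + 1L
          }
          if (i <= n && trimws(lines[i]) == "stop_") i <- i + 1L
          if (length(rows)) {
            tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
            names(tab) <- cols[seq_len(ncol(tab))]
            frame$loops[[length(frame$loops) + 1L]] <- tab
          }
        } else i <- i + 1L
      }
      frames[[length(frames) + 1L]] <- frame
    }
    i <- i + 1L
  }
  frames
}

star_tag <- function(frame, suffixes) {
  for (nm in names(frame$tags)) {
    base <- tolower(sub("^.*\\.", "", nm))
    if (base %in% tolower(suffixes)) return(frame$tags[[nm]])
  }
  NULL
}

#' Read heteronuclear T2/R2 relaxation data from an NMR-STAR file
#'
#' Extracts per-residue transverse relaxation data from NMR-STAR 3.1
#' heteronuclear T2 (or R2) save-frames, the dialect used by BMRB archive
#' entries. When the frame stores relaxation times (`T2_val_units` of `s`
#' or `ms`) values are converted to rates, \eqn{R_2 = 1/T_2}; frames
#' storing rates (`s-1`) are taken as-is. The spectrometer frequency is read
#' from the frame (`Spectrometer_frequency_1H`); frames at several fields
#' yield several record sets.
#'
#' @param path NMR-STAR file.
#' @param field_mhz optional override used when a frame lacks a
#'   spectrometer frequency.
#' @return data.frame of records as in [read_relaxation_csv()].
#' @export
read_nmrstar_relaxation <- function(path, field_mhz = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  frames <- parse_star_saveframes(readLines(path, warn = FALSE))
  is_relax <- function(fr) {
    cat <- tolower(star_tag(fr, "Sf_category") %||% "")
    grepl("t2|r2", cat) && grepl("relax", cat)
  }
  frames <- Filter(is_relax, frames)
  if (!length(frames))
    stop("no heteronuclear T2/R2 relaxation save-frame found in file",
         call. = FALSE)
  recs <- list()
  for (fr in frames) {
    freq <- suppressWarnings(as.numeric(star_tag(fr, "Spectrometer_frequency_1H")))
    if (is.null(freq) || !length(freq) || is.na(freq)) {
      if (is.null(field_mhz))
        stop(sprintf(paste0("save-frame '%s' has no Spectrometer_frequency_1H; ",
                            "supply the field explicitly (field_mhz / --field)"),
                     fr$name), call. = FALSE)
      freq <- field_mhz
    }
    units <- tolower(star_tag(fr, c("T2_val_units", "Val_units")) %||% "s-1")
    loop <- NULL
    for (lp in fr$loops) {
      base <- tolower(sub("^.*\\.", "", names(lp)))
      if (any(base %in% c("val", "t2_val")) &&
          any(base %in% c("comp_index_id", "seq_id"))) { loop <- lp; break }
    }
    if (is.null(loop)) next
    base <- tolower(sub("^.*\\.", "", names(loop)))
    getcol <- function(cands) {
      j <- which(base %in% tolower(cands))
      if (length(j)) loop[[j[1]]] else NA
    }
    val <- suppressWarnings(as.numeric(getcol(c("Val", "T2_val"))))
    err <- suppressWarnings(as.numeric(getcol(c("Val_err", "T2_val_err"))))
    resid <- suppressWarnings(as.integer(getcol(c("Comp_index_ID", "Seq_ID"))))
    resname <- as.character(getcol(c("Comp_ID")))
    conv <- switch(units,
                   "s"   = function(v) 1 / v,
                   "ms"  = function(v) 1000 / v,
                   "s-1" = identity,
                   "1/s" = identity,
                   identity)
    zero_time <- units %in% c("s", "ms") & !is.na(val) & val == 0
    if (any(zero_time)) {
      warning(sprintf("%d zero T2 value(s) skipped in save-frame '%s'",
                      sum(zero_time), fr$name), call. = FALSE)
    }
    keep <- !is.na(val) & !zero_time
    R2 <- conv(val[keep])
    R2e <- if (all(is.na(err))) rep(NA_real_, sum(keep)) else {
      # first-order error propagation through the reciprocal for times
      if (units %in% c("s", "ms")) conv(val[keep])^2 * err[keep] /
        (if (units == "ms") 1000 else 1) else err[keep]
    }
    recs[[length(recs) + 1L]] <- data.frame(
      residue = resid[keep],
      resname = if (length(resname) > 1 || !is.na(resname[1])) resname[keep] else NA,
      field_MHz = freq, R2 = R2, R2_err = R2e, R1 = NA_real_,
      hetNOE = NA_real_, region = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(recs))
    stop("relaxation save-frame(s) found but no per-residue value loop",
         call. = FALSE)
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# group proton frequencies agreeing within 0.5 MHz under one representative
canonical_fields <- function(mhz) {
  u <- sort(unique(mhz))
  rep_of <- numeric(0)
  for (f in u) {
    if (!length(rep_of) || f - rep_of[length(rep_of)] > 0.5)
      rep_of <- c(rep_of, f)
  }
  vapply(mhz, function(f) rep_of[which.min(abs(rep_of - f))], numeric(1))
}

#' Per-residue effective correlation times from a relaxation table
#'
#' Applies one of the four estimators to every record, producing a table of
#' \eqn{\tau_{\mathrm{eff}}} estimates. Input R2 values are treated as the
#' exchange-free \eqn{R_2^\circ} except for the `"rex-corrected"` estimator,
#' which pools all fields of a residue (grouping frequencies within 0.5 MHz
#' as one field) to separate the exchange contribution. Non-physical
#' estimates are reported flagged, never clamped or dropped; for the linear
#' estimator, `R2_err` is propagated as \eqn{\sigma_\tau = k\,\sigma_{R_2}}.
#'
#' @param records data.frame from [read_relaxation_csv()] /
#'   [read_nmrstar_relaxation()].
#' @param estimator one of `"linear"`, `"fitted"`, `"one-timescale"`,
#'   `"rex-corrected"`.
#' @param constants an [nmr_constants()] object.
#' @return data.frame with columns `residue`, `field_MHz` (NA for the
#'   multi-field estimator), `estimator`, `tau_ns`, `tau_err_ns`,
#'   `rex_s1` (per-field exchange rate, rex-corrected only), `flag`,
#'   `region`.
#' @examples
#' rec <- data.frame(residue = 1, field_MHz = 300, R2 = 10)
#' per_residue_tau_table(rec, "linear")  # 8.4 ns
#' @export
per_residue_tau_table <- function(records,
                                  estimator = c("linear", "fitted",
                                                "one-timescale", "rex-corrected"),
                                  constants = nmr_constants()) {
  estimator <- match.arg(estimator)
  stopifnot(is.data.frame(records), all(c("residue", "field_MHz", "R2") %in%
                                          names(records)))
  if (!"R2_err" %in% names(records)) records$R2_err <- NA_real_
  if (!"region" %in% names(records)) records$region <- NA_character_
  if (estimator == "rex-corrected") {
    records$field_grp <- canonical_fields(records$field_MHz)
    out <- lapply(split(records, records$residue), function(rr) {
      if (length(unique(rr$field_grp)) < 2L)
        stop(sprintf(paste0("residue %d has data at %d distinct field(s); the ",
                            "rex-corrected estimator requires >= 2"),
                     rr$residue[1], length(unique(rr$field_grp))), call. = FALSE)
      est <- tau_eff_rex_corrected(rr$R2, rr$field_MHz, constants)
      data.frame(residue = rr$residue[1], field_MHz = NA_real_,
                 estimator = "rex-corrected", tau_ns = est$tauEff * 1e9,
                 tau_err_ns = NA_real_,
                 rex_s1 = paste(sprintf("%s:%.4g", names(est$rex), est$rex),
                                collapse = ";"),
                 flag = est$flag, region = rr$region[1],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    return(out[order(out$residue), , drop = FALSE])
  }
  one <- function(i) {
    r <- records[i, ]
    est <- switch(estimator,
      "linear" = tau_eff_linear(r$R2, r$field_MHz, R2_err = r$R2_err,
                                constants = constants),
      "fitted" = tau_eff_fitted(r$R2, r$field_MHz),
      "one-timescale" = tau_eff_one_timescale(r$R2, r$field_MHz, constants))
    err <- if (!is.null(est$details$tau_err)) est$details$tau_err * 1e9 else NA_real_
    data.frame(residue = r$residue, field_MHz = r$field_MHz,
               estimator = estimator, tau_ns = est$tauEff * 1e9,
               tau_err_ns = err, rex_s1 = NA_character_, flag = est$flag,
               region = r$region, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(records)), one))
  rownames(out) <- NULL
  out
}

#' Region-wise summary of effective correlation times
#'
#' Averages per-residue \eqn{\tau_{\mathrm{eff}}} over user-assigned sequence
#' regions (e.g. manually assigned folded and disordered stretches) and
#' correlates region size with mean \eqn{\tau_{\mathrm{eff}}} within each
#' region class — the analysis used to ask whether disordered-region
#' dynamics depend on region size. Flagged (non-physical) estimates are
#' excluded from the means.
#'
#' @param tau_table output of [per_residue_tau_table()].
#' @param regions data.frame with columns `residue`, `region` (label unique
#'   to one contiguous stretch) and `class` (e.g. `"folded"` /
#'   `"disordered"`); each residue belongs to at most one region.
#' @return list with `summary` (one row per region: `region`, `class`,
#'   `first_residue`, `last_residue`, `size`, `mean_tau_ns`, `sd_tau_ns`)
#'   and `correlations` (per class: Pearson `r` and two-sided `p` of region
#'   size vs mean \eqn{\tau_{\mathrm{eff}}}; `NA` with fewer than 3
#'   regions).
#' @export
region_summary <- function(tau_table, regions) {
  stopifnot(is.data.frame(regions),
            all(c("residue", "region", "class") %in% names(regions)))
  if (anyDuplicated(regions$residue))
    stop("each residue may be assigned to at most one region", call. = FALSE)
  merged <- merge(tau_table, regions, by = "residue")
  ok <- is.na(merged$flag)
  merged <- merged[ok, , drop = FALSE]
  summ <- do.call(rbind, lapply(split(merged, merged$region.y), function(g) {
    data.frame(region = g$region.y[1], class = g$class[1],
               first_residue = min(g$residue), last_residue = max(g$residue),
               size = length(unique(g$residue)),
               mean_tau_ns = mean(g$tau_ns),
               sd_tau_ns = if (nrow(g) > 1) stats::sd(g$tau_ns) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  cors <- do.call(rbind, lapply(split(summ, summ$class), function(s) {
    if (nrow(s) < 3L || stats::sd(s$size) == 0 || stats::sd(s$mean_tau_ns) == 0) {
      data.frame(class = s$class[1], n_regions = nrow(s), r = NA_real_,
                 p = NA_real_, stringsAsFactors = FALSE)
    } else {
      ct <- stats::cor.test(s$size, s$mean_tau_ns, method = "pearson")
      data.frame(class = s$class[1], n_regions = nrow(s),
                 r = unname(ct$estimate), p = ct$p.value,
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(cors) <- NULL
  list(summary = summ, correlations = cors)
}
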