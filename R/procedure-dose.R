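#' Parse a gantry angulation label
#'
#' Accepts \code{"PA"}, single components \code{"LAO31"}, \code{"RAO 33"},
#' \code{"CRA40"}, \code{"CAU 4"} (an optional degree sign is allowed), or
#' a pair joined by \code{"/"}. Sign convention: LAO and CRA positive, RAO
#' and CAU negative.
#'
#' @param label angulation label text.
#' @return named numeric \code{c(lateral, axial)} in degrees.
#' @examples
#' parseAngulation("LAO31/CAU28")  # c(31, -28)
#' parseAngulation("PA")           # c(0, 0)
#' @export
parseAngulation <- function(label) {
  raw <- label
  s <- trimws(gsub("\u00b0", "", label))
  if (toupper(s) == "PA") return(c(lateral = 0, axial = 0))
  parts <- strsplit(s, "/", fixed = TRUE)[[1]]
  lateral <- NA_real_; axial <- NA_real_
  for (p in toupper(parts)) {
    m <- regmatches(p, regexec("^\\s*(LAO|RAO|CRA|CAU)\\s*([0-9]+(?:\\.[0-9]+)?)\\s*$",
                               p))[[1]]
    if (length(m) != 3)
      stop("cannot parse angulation label: '", raw, "'")
    ang <- as.numeric(m[3])
    switch(m[2],
      LAO = { if (!is.na(lateral)) stop("duplicate lateral component in '",
                                        raw, "'"); lateral <- ang },
      RAO = { if (!is.na(lateral)) stop("duplicate lateral component in '",
                                        raw, "'"); lateral <- -ang },
      CRA = { if (!is.na(axial)) stop("duplicate axial component in '",
                                      raw, "'"); axial <- ang },
      CAU = { if (!is.na(axial)) stop("duplicate axial component in '",
                                      raw, "'"); axial <- -ang })
  }
  out <- c(lateral = ifelse(is.na(lateral), 0, lateral),
           axial = ifelse(is.na(axial), 0, axial))
  if (any(abs(out) > 90)) stop("|angulation| must be <= 90 degrees: '",
                               raw, "'")
  out
}

#' Read a procedure acquisition log from CSV
#'
#' Expected header: \code{label,angulation,sid_cm,kv,ma,ms,frames,time_s,
#' dap_gycm2,fov_cm}. The angulation column is parsed into signed
#' lateral/axial degrees (see [parseAngulation()]).
#'
#' @param path CSV path.
#' @return data.frame with the log columns plus lateral_deg and axial_deg.
#' @export
readAcquisitionLog <- function(path) {
  if (!file.exists(path)) stop("acquisition log not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "angulation", "sid_cm", "kv", "ma", "ms", "frames",
            "time_s", "dap_gycm2", "fov_cm")
  if (!all(need %in% names(df)))
    stop("acquisition log must have columns: ", paste(need, collapse = ","))
  validateAcquisitionLog(within(df, {
    ang <- t(vapply(angulation, parseAngulation, numeric(2)))
    lateral_deg <- ang[, 1]
    axial_deg <- ang[, 2]
    rm(ang)
  }))
}

validateAcquisitionLog <- function(df) {
  if (any(df$dap_gycm2 < 0)) stop("DAP must be >= 0")
  if (any(df$fov_cm <= 0)) stop("FOV must be > 0")
  if (any(df$frames < 0)) stop("frame counts must be >= 0")
  df
}

#' The packaged mock coronary-angiography acquisition log
#'
#' Nine ABC-mode cine acquisitions (angulation, SID, tube factors, frames,
#' time, DAP, FOV) recorded during a mock procedure on the phantom; total
#' DAP 14.06 Gy.cm2. All acquisitions use a 15 cm FOV except #9 (the left
#' ventricle view) at 23 cm.
#'
#' @return data.frame as from [readAcquisitionLog()].
#' @export
mockProcedureLog <- function() {
  readAcquisitionLog(system.file("extdata", "mock_procedure_log.csv",
                                 package = "filmdose", mustWork = TRUE))
}

#' Total dose-area product of an acquisition log
#'
#' @param records acquisition log data.frame (column dap_gycm2).
#' @return sum of per-record DAP, Gy.cm2 (0 for an empty log).
#' @export
totalDap <- function(records) {
  if (is.null(records) || nrow(records) == 0) return(0)
  sum(records$dap_gycm2)
}

#' Read a conversion-factor table from CSV
#'
#' Expected header: \code{lateral_deg,axial_deg,fov_cm,factor_left,
#' factor_right,factor_overall} (factors in mGy per Gy.cm2).
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
readFactorTable <- function(path) {
  if (!file.exists(path)) stop("factor table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lateral_deg", "axial_deg", "fov_cm", "factor_left",
            "factor_right", "factor_overall")
  if (!all(need %in% names(df)))
    stop("factor CSV must have columns: ", paste(need, collapse = ","))
  if (any(df[, c("factor_left", "factor_right", "factor_overall")] < 0))
    stop("conversion factors must be >= 0")
  df
}

#' Synthetic demonstration conversion-factor table
#'
#' A demo-only table covering the mock-procedure angulations at 15 cm FOV
#' with plausible magnitudes; the values are synthetic (the measured
#' per-angulation factors exist only graphically in the source experiment)
#' and each row's overall factor is mass-consistent
#' (\code{0.45 left + 0.55 right}).
#'
#' @return data.frame as from [readFactorTable()].
#' @export
demoFactorTable <- function() {
  readFactorTable(system.file("extdata", "demo_factor_table_synthetic.csv",
                              package = "filmdose", mustWork = TRUE))
}

#' Match an acquisition to a conversion-factor entry
#'
#' Matching policy, in order: exact (angulation, FOV) match; same
#' angulation at the nearest available FOV (FOV fallback, flagged); nearest
#' angulation by Euclidean distance in (lateral, axial) degrees within
#' \code{toleranceDeg}, tie-broken by FOV proximity (flagged). Beyond the
#' tolerance, an error lists the nearest candidates.
#'
#' @param table conversion-factor table (see [readFactorTable()]).
#' @param record one acquisition (a one-row data.frame or list with
#'   lateral_deg, axial_deg, fov_cm).
#' @param toleranceDeg angular matching tolerance, degrees (default 6).
#' @return list with \code{entry} (the matched table row), \code{index}
#'   (its row number) and \code{fallback_used}.
#' @export
matchFactor <- function(table, record, toleranceDeg = 6) {
  if (is.null(table) || nrow(table) == 0) stop("factor table is empty")
  lat <- record$lateral_deg; ax <- record$axial_deg; fov <- record$fov_cm
  dAng <- sqrt((table$lateral_deg - lat)^2 + (table$axial_deg - ax)^2)
  dFov <- abs(table$fov_cm - fov)
  epsA <- 1e-6
  same <- dAng <= epsA
  if (any(same & dFov <= 1e-6)) {
    i <- which(same & dFov <= 1e-6)[1]
    return(list(entry = table[i, , drop = FALSE], index = i,
                fallback_used = FALSE))
  }
  if (any(same)) {                       # FOV fallback first
    cand <- which(same)
    i <- cand[which.min(dFov[cand])]
    return(list(entry = table[i, , drop = FALSE], index = i,
                fallback_used = TRUE))
  }
  within <- which(dAng <= toleranceDeg)
  if (length(within)) {                  # nearest-angulation fallback
    i <- within[order(dAng[within], dFov[within])][1]
    return(list(entry = table[i, , drop = FALSE], index = i,
                fallback_used = TRUE))
  }
  near <- order(dAng)[seq_len(min(3, nrow(table)))]
  stop("no factor entry within ", toleranceDeg,
       " degrees of (", lat, ", ", ax, "); nearest candidates: ",
       paste(sprintf("(%g, %g) at %.1f deg", table$lateral_deg[near],
                     table$axial_deg[near], dAng[near]), collapse = "; "))
}

#' Reconstruct procedure breast dose from a log and a factor table
#'
#' Each acquisition contributes \code{DAP x factor} per breast side (and
#' overall); totals are the sums over acquisitions.
#'
#' @param records acquisition log (see [readAcquisitionLog()]).
#' @param table conversion-factor table (see [readFactorTable()]).
#' @param toleranceDeg angular matching tolerance (see [matchFactor()]).
#' @return a \linkS4class{ProcedureDoseEstimate}.
#' @export
estimateBreastDose <- function(records, table, toleranceDeg = 6) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, , drop = FALSE]
    m <- tryCatch(matchFactor(table, r, toleranceDeg),
                  error = function(e)
                    stop("acquisition '", r$label, "': ",
                         conditionMessage(e), call. = FALSE))
    data.frame(label = r$label,
               dap_gycm2 = r$dap_gycm2,
               matched_row = m$index,
               fallback_used = m$fallback_used,
               dose_left = r$dap_gycm2 * m$entry$factor_left,
               dose_right = r$dap_gycm2 * m$entry$factor_right,
               dose_overall = r$dap_gycm2 * m$entry$factor_overall,
               stringsAsFactors = FALSE)
  })
  pa <- do.call(rbind, rows)
  new("ProcedureDoseEstimate",
      perAcquisition = pa,
      dLeft = sum(pa$dose_left), dRight = sum(pa$dose_right),
      dOverall = sum(pa$dose_overall), totalDap = totalDap(records))
}

#' Effective dose from DAP via a scalar conversion factor
#'
#' @param dap dose-area product, Gy.cm2 (>= 0).
#' @param k DAP-to-effective-dose conversion factor, mSv per Gy.cm2
#'   (default 0.2, a published value for coronary angiography).
#' @return effective dose, mSv.
#' @examples
#' effectiveDoseFromDap(82)  # 16.4 mSv
#' @export
effectiveDoseFromDap <- function(dap, k = 0.2) {
  if (any(dap < 0) || any(k < 0)) stop("dap and k must be >= 0")
  dap * k
}
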