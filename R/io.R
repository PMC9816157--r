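#' Read an extended XYZ trajectory with per-atom charges
#'
#' Parses the extended XYZ dialect: per frame, a particle count line, a
#' comment line with `Lattice="ax ay az bx by bz cx cy cz"`, optional
#' `Time=<fs>` and a `Properties=` descriptor, then one line per atom with
#' species, x, y, z and charge columns. Only cubic lattices are accepted.
#' Errors name the offending line.
#'
#' @param path file path.
#' @return list of [configuration] frames.
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop(sprintf("line %d: expected a particle count", i))
    n <- as.integer(lines[i])
    if (i + 1L > length(lines)) stop("truncated file: missing comment line")
    header <- lines[i + 1L]
    lat <- regmatches(header,
                      regexpr('Lattice="[^"]+"', header))
    if (!length(lat))
      stop(sprintf('line %d: missing Lattice="..." header', i + 1L))
    lv <- as.numeric(strsplit(sub('Lattice="([^"]+)"', "\\1", lat),
                              "\\s+")[[1]])
    if (length(lv) != 9L) stop(sprintf("line %d: Lattice needs 9 numbers",
                                       i + 1L))
    m <- matrix(lv, 3, 3, byrow = TRUE)
    if (max(abs(m - diag(diag(m)))) > 1e-10 ||
        max(abs(diag(m) - m[1, 1])) > 1e-10)
      stop(sprintf("line %d: only cubic lattices are supported", i + 1L))
    tm <- regmatches(header, regexpr("Time=[-0-9.eE+]+", header))
    time <- if (length(tm)) as.numeric(sub("Time=", "", tm)) else
      length(frames)
    body <- lines[i + 1L + seq_len(n)]
    if (length(body) < n || anyNA(body))
      stop(sprintf("truncated frame starting at line %d", i))
    parts <- strsplit(trimws(body), "\\s+")
    ncol <- lengths(parts)
    if (any(ncol < 5L))
      stop(sprintf("line %d: need species, x, y, z, charge columns",
                   i + 1L + which(ncol < 5L)[1]))
    species <- vapply(parts, `[`, character(1), 1L)
    num <- t(vapply(parts, function(p) as.numeric(p[2:5]), numeric(4)))
    if (anyNA(num))
      stop(sprintf("non-numeric coordinate or charge in frame at line %d",
                   i))
    frames[[length(frames) + 1L]] <-
      configuration(num[, 1:3, drop = FALSE], num[, 4], m[1, 1],
                    species = species, time = time)
    i <- i + 2L + n
  }
  frames
}

#' Write a trajectory in extended XYZ format with charges
#'
#' @param traj list of [configuration] frames.
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (frame in traj) {
    L <- frame$box_edge
    writeLines(as.character(nrow(frame$positions)), con)
    writeLines(sprintf(
      paste0('Lattice="%.12g 0 0 0 %.12g 0 0 0 %.12g" ',
             'Properties=species:S:1:pos:R:3:charge:R:1 Time=%.12g'),
      L, L, L, frame$time), con)
    writeLines(sprintf("%s %.12g %.12g %.12g %.12g", frame$species,
                       frame$positions[, 1], frame$positions[, 2],
                       frame$positions[, 3], frame$charges), con)
  }
  invisible(path)
}

#' Write or read an EFG series as CSV
#'
#' Columns: `time_fs`, `probe`, then the six independent tensor components
#' `xx, yy, zz, xy, xz, yz` (e/A^3). A `# units:` comment line precedes the
#' header.
#'
#' @param series an `efg_series`.
#' @param path file path.
#' @return `path` (write) or an `efg_series` (read).
#' @export
write_efg_series_csv <- function(series, path) {
  d <- dim(series$comps)
  rows <- do.call(rbind, lapply(seq_len(d[3]), function(j)
    data.frame(time_fs = series$times,
               probe = if (is.null(series$probes)) j else series$probes[j],
               series$comps[, , j, drop = TRUE])))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units: time fs, EFG components e/A^3", con)
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_efg_series_csv
#' @export
read_efg_series_csv <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#")
  need <- c("time_fs", "probe", tensor_comp_names)
  if (!all(need %in% names(tab)))
    stop("EFG series CSV must have columns: ", paste(need, collapse = ", "))
  probes <- sort(unique(tab$probe))
  times <- sort(unique(tab$time_fs))
  comps <- array(NA_real_, c(length(times), 6L, length(probes)),
                 dimnames = list(NULL, tensor_comp_names, NULL))
  for (j in seq_along(probes)) {
    sub <- tab[tab$probe == probes[j], ]
    sub <- sub[order(sub$time_fs), ]
    comps[, , j] <- as.matrix(sub[, tensor_comp_names])
  }
  dt <- if (length(times) > 1L) times[2] - times[1] else NA_real_
  new_efg_series(comps, dt, times = times, probes = probes)
}

#' Write or read a stress series as CSV
#'
#' Columns `time_fs, sxx, sxy, sxz, syx, syy, syz, szx, szy, szz` (Pa);
#' box volume (m^3) and temperature (K) are carried in `# units:` metadata
#' comment lines.
#'
#' @param series a [stress_series].
#' @param path file path.
#' @return `path` (write) or a [stress_series] (read).
#' @export
write_stress_csv <- function(series, path) {
  s <- series$stress
  n <- dim(s)[1]
  tab <- data.frame(time_fs = (seq_len(n) - 1L) * series$dt,
                    sxx = s[, 1, 1], sxy = s[, 1, 2], sxz = s[, 1, 3],
                    syx = s[, 2, 1], syy = s[, 2, 2], syz = s[, 2, 3],
                    szx = s[, 3, 1], szy = s[, 3, 2], szz = s[, 3, 3])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# units: time fs, stress Pa",
               sprintf("# volume_m3: %.15g", series$volume),
               sprintf("# temperature_K: %.15g", series$temperature)), con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stress_csv
#' @export
read_stress_csv <- function(path) {
  hdr <- readLines(path, n = 10L)
  vol <- as.numeric(sub("# volume_m3: ", "",
                        grep("^# volume_m3:", hdr, value = TRUE)[1]))
  temp <- as.numeric(sub("# temperature_K: ", "",
                         grep("^# temperature_K:", hdr, value = TRUE)[1]))
  if (is.na(vol) || is.na(temp))
    stop("stress CSV must carry # volume_m3: and # temperature_K: headers")
  tab <- utils::read.csv(path, comment.char = "#")
  n <- nrow(tab)
  s <- array(0, c(n, 3L, 3L))
  cols <- matrix(c("sxx", "sxy", "sxz", "syx", "syy", "syz",
                   "szx", "szy", "szz"), 3, 3, byrow = TRUE)
  for (r in 1:3) for (cc in 1:3) s[, r, cc] <- tab[[cols[r, cc]]]
  dt <- if (n > 1L) tab$time_fs[2] - tab$time_fs[1] else 1
  stress_series(s, dt, vol, temp)
}

#' Write or read an ACF as CSV
#'
#' Columns `lag_fs, value, stderr, n_origins`.
#'
#' @param acf a `tensor_acf`.
#' @param path file path.
#' @return `path` (write) or a `tensor_acf` (read).
#' @export
write_acf_csv <- function(acf, path) {
  utils::write.csv(data.frame(lag_fs = acf$lag_fs, value = acf$value,
                              stderr = acf$stderr,
                              n_origins = acf$n_origins),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_acf_csv
#' @export
read_acf_csv <- function(path) {
  tab <- utils::read.csv(path)
  structure(list(lag_fs = tab$lag_fs, value = tab$value,
                 stderr = tab$stderr, n_origins = tab$n_origins,
                 c0 = tab$value[1],
                 dt = if (nrow(tab) > 1L) tab$lag_fs[2] - tab$lag_fs[1]
                      else NA_real_,
                 n_probes = NA_integer_),
            class = "tensor_acf")
}

#' Read or write a Sternheimer pair table CSV
#'
#' Schema: columns `config_id, probe_id, comp, v_ext, v_ai`; a `# units:`
#' comment line declares the EFG units.
#'
#' @param table an [efg_pair_table].
#' @param path file path.
#' @return `path` (write) or an [efg_pair_table] (read).
#' @export
write_pair_table_csv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s", attr(table, "units") %||% "e/A^3"), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_pair_table_csv
#' @export
read_pair_table_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  units <- if (grepl("^# units:", hdr)) sub("^# units:\\s*", "", hdr)
           else "e/A^3"
  tab <- utils::read.csv(path, comment.char = "#")
  efg_pair_table(tab$config_id, tab$probe_id, tab$comp, tab$v_ext,
                 tab$v_ai, units = units)
}

#' Write a structured analysis report as YAML
#'
#' @param report named list (from [run_pipeline] or assembled manually).
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_report_yaml <- function(report, path) {
  writeLines(yaml::as.yaml(report, precision = 12), path)
  invisible(path)
}
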