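# Plain-text external interfaces: TSV work tables, charge-set tables,
# JSON-lines restart pools with a JSON sidecar, gap-series tables, reduced
# energy matrices, YAML system fixtures, JSON estimates.  All numeric output
# goes through one canonical formatter so that write -> read -> write is
# byte-identical.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

#' Write / read a work table
#'
#' Tab-separated text with one row per switch and a header line naming the
#' units (`final_work_kcal_mol`).
#'
#' @param x A `work_table` from [run_switch_ensemble()].
#' @param path Output file.
#' @return `write_work_table` returns `path` invisibly; `read_work_table`
#'   returns a `work_table` data frame.
#' @export
write_work_table <- function(x, path) {
  df <- as.data.frame(x)
  df$final_work_kcal_mol <- fmt_num(df$final_work_kcal_mol)
  df$seed <- fmt_num(df$seed)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_work_table
#' @export
read_work_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("switch_id", "direction", "schedule", "n_steps",
            "final_work_kcal_mol", "start_replicate", "start_step", "seed")
  if (!all(need %in% names(df)))
    stopf("input error: work table %s lacks columns: %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  class(df) <- c("work_table", "data.frame")
  df
}

#' Write / read a charge-set table
#'
#' Plain-text table with columns `atom_label`, `charge_e`, `std_e`; comment
#' headers record the source, the number of averaged configurations and the
#' net charge.  Round-trips bit-exactly.
#'
#' @param x A [charge_set()].
#' @param path File path.
#' @return `write_charge_set` returns `path` invisibly; `read_charge_set`
#'   a `charge_set`.
#' @export
write_charge_set <- function(x, path) {
  stopifnot(inherits(x, "charge_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# source: %s", x$source),
    sprintf("# n_configs: %d", x$n_configs_averaged),
    sprintf("# net_charge: %s", fmt_num(x$net_charge)),
    "atom_label\tcharge_e\tstd_e"), con)
  std <- if (is.null(x$per_atom_std)) rep(0, length(x$charges)) else x$per_atom_std
  writeLines(paste(x$atom_labels, fmt_num(x$charges), fmt_num(std),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_charge_set
#' @export
read_charge_set <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "",
                           grep(sprintf("^# %s:", key), hdr, value = TRUE)[1])
  df <- read.delim(text = lines[!grepl("^#", lines)], stringsAsFactors = FALSE)
  charge_set(df$charge_e, atom_labels = df$atom_label, source = get("source"),
             n_configs_averaged = as.integer(get("n_configs")),
             per_atom_std = df$std_e,
             net_charge = as.numeric(get("net_charge")), neutralize = FALSE)
}

#' Write / read a restart pool
#'
#' JSON-lines records (one configuration per line: time stamp, coordinates
#' or orientations, velocities, provenance) plus a `<path>.meta.json`
#' sidecar with the pool-level metadata (kind, coupling value, sampler
#' settings, site positions).
#'
#' @param pool A `restart_pool`.
#' @param path File path for the JSON-lines records.
#' @return `write_pool` returns `path` invisibly; `read_pool` a
#'   `restart_pool`.
#' @export
write_pool <- function(pool, path) {
  stopifnot(inherits(pool, "restart_pool"))
  meta <- list(kind = pool$kind, lambda = pool$lambda,
               source_label = pool$source_label, n_sites = pool$n_sites,
               n_configs = length(pool),
               sites = pool$sites,
               settings = unclass(pool$settings))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(length(pool))) {
    rec <- list(time_fs = pool$time_fs[i], replicate = pool$replicate[i],
                step = pool$step[i])
    if (pool$kind == "harmonic") {
      rec$x <- pool$data$x[i]; rec$v <- pool$data$v[i]
    } else {
      rec$orientations <- as.numeric(pool$data$orientations[, , i])
      rec$angvel <- as.numeric(pool$data$angvel[, , i])
    }
    if (!is.null(pool$u_low)) { rec$u_low <- pool$u_low[i]; rec$u_high <- pool$u_high[i] }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  n <- length(recs)
  grab <- function(f) vapply(recs, function(r) r[[f]], 0)
  settings <- if (!is.null(meta$settings) && length(meta$settings))
    do.call(sampler_settings, meta$settings[!vapply(meta$settings, is.null, TRUE)])
  else NULL
  if (meta$kind == "harmonic") {
    data <- list(x = grab("x"), v = grab("v"))
    sites <- NULL
  } else {
    S <- meta$n_sites
    u <- array(unlist(lapply(recs, `[[`, "orientations")), dim = c(3, max(S, 1), n))
    w <- array(unlist(lapply(recs, `[[`, "angvel")), dim = c(3, max(S, 1), n))
    data <- list(orientations = u, angvel = w)
    sites <- if (!is.null(meta$sites)) matrix(unlist(meta$sites), ncol = 3) else NULL
  }
  ul <- if (!is.null(recs[[1]]$u_low)) grab("u_low") else NULL
  uh <- if (!is.null(recs[[1]]$u_high)) grab("u_high") else NULL
  new_restart_pool(meta$kind, meta$lambda, data, grab("replicate"),
                   grab("step"), grab("time_fs"), settings,
                   meta$source_label, n_sites = meta$n_sites %||% 0L,
                   sites = sites, u_low = ul, u_high = uh)
}

#' Write / read an energy-gap trajectory table
#'
#' Tab-separated: column 1 is the time in fs, one further column per
#' trajectory.
#'
#' @param gaps Matrix (rows = time points, columns = trajectories).
#' @param times Time grid (fs).
#' @param path File path.
#' @return `write_gap_series` returns `path` invisibly; `read_gap_series`
#'   a list with `times` and `gaps`.
#' @export
write_gap_series <- function(gaps, times, path) {
  gaps <- as.matrix(gaps)
  df <- cbind(time_fs = fmt_num(times),
              matrix(fmt_num(gaps), nrow = nrow(gaps),
                     dimnames = list(NULL, paste0("traj_", seq_len(ncol(gaps))))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gap_series
#' @export
read_gap_series <- function(path) {
  df <- read.delim(path)
  list(times = df[[1]], gaps = as.matrix(df[, -1, drop = FALSE]))
}

#' Write / read a reduced-energy matrix for staged BAR
#'
#' Tab-separated: rows are samples, the `state` column gives the index of
#' the state each sample was drawn from (plus its replicate), and one column
#' per state holds the sample's reduced energy there; the header records the
#' coupling values.
#'
#' @param staged A `staged_energies` object from [sample_staged()].
#' @param path File path.
#' @return `write_energy_matrix` returns `path` invisibly;
#'   `read_energy_matrix` a `staged_energies` object (beta recovered from
#'   the sidecar-free header comment).
#' @export
write_energy_matrix <- function(staged, path) {
  stopifnot(inherits(staged, "staged_energies"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# beta: %s", fmt_num(staged$beta)), con)
  writeLines(paste(c("state", "replicate",
                     sprintf("lambda_%s", fmt_num(staged$lambdas))),
                   collapse = "\t"), con)
  for (s in seq_along(staged$u)) {
    m <- staged$u[[s]]
    reps <- staged$replicates[[s]]
    for (i in seq_len(nrow(m)))
      writeLines(paste(c(s, reps[i], fmt_num(m[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_energy_matrix
#' @export
read_energy_matrix <- function(path) {
  lines <- readLines(path)
  beta <- as.numeric(sub("^# beta: ", "", lines[1]))
  df <- read.delim(text = lines[-1])
  lam_cols <- grep("^lambda_", names(df))
  lambdas <- as.numeric(sub("^lambda_", "", names(df)[lam_cols]))
  states <- sort(unique(df$state))
  u <- lapply(states, function(s) {
    m <- as.matrix(df[df$state == s, lam_cols, drop = FALSE])
    dimnames(m) <- list(NULL, sprintf("lambda_%g", lambdas))
    m
  })
  reps <- lapply(states, function(s) df$replicate[df$state == s])
  structure(list(u = u, lambdas = lambdas, beta = beta, replicates = reps),
            class = "staged_energies")
}

#' Write / read a dual-level system as a YAML fixture
#'
#' Structured configuration with sections `thermo`, `solute`, `solvent` and
#' `high_level` (dipole-bath systems) or `harmonic` parameters; all fields
#' in the package units (kcal/mol, Angstrom, e, fs, Kelvin).
#'
#' @param system A `dual_level_system`.
#' @param path File path.
#' @return `write_system` returns `path` invisibly; `read_system` a
#'   `dual_level_system`.
#' @export
write_system <- function(system, path) {
  stopifnot(inherits(system, "dual_level_system"))
  if (system$kind == "harmonic") {
    doc <- list(kind = "harmonic",
                thermo = list(temperature = system$thermo$temperature),
                harmonic = list(k_low = system$k_low, k_high = system$k_high,
                                offset = system$x0_high - system$x0_low,
                                mass = system$mass, friction = system$friction),
                labels = list(low = system$label_low, high = system$label_high))
  } else {
    doc <- list(
      kind = "dipole_bath",
      thermo = list(temperature = system$thermo$temperature),
      solute = list(coordinates = apply(system$solute$coordinates, 1,
                                        as.list, simplify = FALSE),
                    base_charges = as.list(system$solute$base_charges),
                    net_charge = system$solute$net_charge,
                    atom_labels = as.list(system$solute$atom_labels),
                    heavy = as.list(system$solute$heavy)),
      solvent = list(site_positions = apply(system$solvent$site_positions, 1,
                                            as.list, simplify = FALSE),
                     dipole_magnitude = system$solvent$dipole_magnitude,
                     rotational_friction = system$solvent$rotational_friction,
                     inertia = system$solvent$inertia),
      high_level = list(response_coefficients =
                          as.list(system$solute$response_coefficients),
                        level_offset = system$offset_high),
      labels = list(low = system$label_low, high = system$label_high))
  }
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' @rdname write_system
#' @export
read_system <- function(path) {
  doc <- yaml::read_yaml(path)
  thermo <- thermo_state(doc$thermo$temperature)
  if (identical(doc$kind, "harmonic")) {
    h <- doc$harmonic
    make_harmonic_pair(h$k_low, h$k_high, offset = h$offset, thermo = thermo,
                       mass = h$mass, friction = h$friction,
                       label_low = doc$labels$low, label_high = doc$labels$high)
  } else if (identical(doc$kind, "dipole_bath")) {
    coords <- do.call(rbind, lapply(doc$solute$coordinates, unlist))
    solute <- solute_spec(coords, unlist(doc$solute$base_charges),
                          unlist(doc$high_level$response_coefficients),
                          net_charge = doc$solute$net_charge,
                          atom_labels = unlist(doc$solute$atom_labels),
                          heavy = unlist(doc$solute$heavy))
    sp <- doc$solvent$site_positions
    sites <- if (length(sp)) do.call(rbind, lapply(sp, unlist)) else NULL
    solvent <- solvent_spec(sites, doc$solvent$dipole_magnitude,
                            doc$solvent$rotational_friction,
                            doc$solvent$inertia)
    make_dipole_bath_system(solute, solvent, thermo = thermo,
                            level_offset = doc$high_level$level_offset %||% 0,
                            label_low = doc$labels$low,
                            label_high = doc$labels$high)
  } else {
    stopf("input error: unknown system kind '%s' in %s", doc$kind, path)
  }
}

#' Write / read a free energy estimate as JSON
#'
#' @param estimate A `free_energy_estimate`.
#' @param path File path.
#' @return `write_estimate` returns `path` invisibly; `read_estimate` a
#'   list.
#' @export
write_estimate <- function(estimate, path) {
  stopifnot(inherits(estimate, "free_energy_estimate"))
  x <- unclass(estimate)
  x$diagnostics <- x$diagnostics[!vapply(x$diagnostics, is.list, TRUE)]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_estimate
#' @export
read_estimate <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
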