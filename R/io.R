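# File formats, configuration and the command-line front end.

P21C_ALIASES <- c("P21/c", "P 21/c", "P 1 21/c 1", "P2(1)/c", "14", "P21/C")

#' Write a crystal structure to CIF
#'
#' Emits the core CIF tags for the cell, the P2\eqn{_1}/c space-group
#' declaration and the fractional atom sites.
#'
#' @param structure A [crystal_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cif <- function(structure, path) {
  cell <- structure$cell
  at <- structure$atoms
  lines <- c(
    "data_phaseseed",
    sprintf("_cell_length_a %.6f", cell$a),
    sprintf("_cell_length_b %.6f", cell$b),
    sprintf("_cell_length_c %.6f", cell$c),
    "_cell_angle_alpha 90.0",
    sprintf("_cell_angle_beta %.6f", cell$beta),
    "_cell_angle_gamma 90.0",
    "_symmetry_space_group_name_H-M 'P 21/c'",
    "_space_group_IT_number 14",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_B_iso_or_equiv",
    "_atom_site_occupancy",
    sprintf("%s%d %s %.6f %.6f %.6f %.4f %.4f",
            at$element, seq_len(nrow(at)), at$element,
            at$x, at$y, at$z, at$b_iso, at$occupancy)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a crystal structure from CIF
#'
#' Minimal core-CIF reader for the cell parameters and fractional atom sites.
#' Only space group P2\eqn{_1}/c (or its Hermann-Mauguin / IT-number aliases,
#' including number 14) is accepted.
#'
#' @param path CIF file path.
#' @return A [crystal_structure()].
#' @export
read_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  getval <- function(tag) {
    hit <- grep(paste0("^\\s*", tag, "\\b"), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^\\s*", tag, "\\s+"), "", hit[1])
  }
  num <- function(tag) {
    v <- getval(tag)
    if (is.na(v)) stopf("read_cif: missing tag %s", tag)
    as.numeric(sub("\\(.*\\)", "", v))
  }
  sg <- c(getval("_symmetry_space_group_name_H-M"),
          getval("_space_group_name_H-M_alt"),
          getval("_space_group_IT_number"),
          getval("_symmetry_Int_Tables_number"))
  sg <- gsub("'|\"", "", sg[!is.na(sg)])
  if (!length(sg)) stopf("read_cif: no space-group declaration found")
  if (!any(trimws(sg) %in% P21C_ALIASES))
    stopf("unsupported space group: %s (only P21/c is handled)", sg[1])
  cell <- unit_cell(num("_cell_length_a"), num("_cell_length_b"),
                    num("_cell_length_c"), num("_cell_angle_beta"))
  # atom loop
  loop_starts <- grep("^\\s*loop_", lines)
  atoms <- NULL
  for (ls in loop_starts) {
    i <- ls + 1L
    tags <- character(0)
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1L
    }
    if (!any(grepl("^_atom_site_fract_x", tags))) next
    rows <- character(0)
    while (i <= length(lines) && nzchar(trimws(lines[i])) &&
           !grepl("^\\s*(_|loop_|data_)", lines[i])) {
      rows <- c(rows, trimws(lines[i])); i <- i + 1L
    }
    tab <- do.call(rbind, strsplit(rows, "\\s+"))
    cn <- function(tag) match(tag, tags)
    sym <- cn("_atom_site_type_symbol")
    if (is.na(sym)) sym <- cn("_atom_site_label")
    atoms <- data.frame(
      element = gsub("[0-9]+$", "", tab[, sym]),
      x = as.numeric(tab[, cn("_atom_site_fract_x")]),
      y = as.numeric(tab[, cn("_atom_site_fract_y")]),
      z = as.numeric(tab[, cn("_atom_site_fract_z")]),
      stringsAsFactors = FALSE)
    bcol <- cn("_atom_site_B_iso_or_equiv")
    if (!is.na(bcol)) atoms$b_iso <- as.numeric(tab[, bcol])
    ocol <- cn("_atom_site_occupancy")
    if (!is.na(ocol)) atoms$occupancy <- as.numeric(tab[, ocol])
    break
  }
  if (is.null(atoms)) stopf("read_cif: no atom site loop found")
  crystal_structure(cell, atoms)
}

#' Write reflections to a SHELX-style .hkl file
#'
#' Fixed-width `3I4,2F8.2` records of `h k l F sigma`, terminated by a row of
#' zeros. Amplitudes are rescaled to fit the field width if necessary.
#'
#' @param rs A `reflection_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hkl <- function(rs, path) {
  refl <- rs$refl
  scale <- 1
  mx <- max(refl$F_obs)
  if (mx >= 9999.99) scale <- 9999 / mx
  lines <- sprintf("%4d%4d%4d%8.2f%8.2f", refl$h, refl$k, refl$l,
                   refl$F_obs * scale, refl$sigma * scale)
  writeLines(c(lines, sprintf("%4d%4d%4d%8.2f%8.2f", 0L, 0L, 0L, 0, 0)), path)
  invisible(path)
}

#' Read a SHELX-style .hkl file
#'
#' Parses fixed-width `3I4,2F8.2` records until the all-zero terminator.
#' Indices are mapped to the canonical Laue 2/m representative; duplicate
#' equivalents are merged by their sigma-weighted mean (plain mean when
#' sigmas are zero), with a warning.
#'
#' @param path Input file path.
#' @return data.frame with columns `h`, `k`, `l` (canonical), `F_obs`,
#'   `sigma`.
#' @export
read_hkl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (ln in seq_along(lines)) {
    s <- lines[ln]
    if (!nzchar(trimws(s))) next
    if (nchar(s) < 28) stopf("read_hkl: malformed line %d (expected 3I4,2F8.2)", ln)
    fields <- c(substr(s, 1, 4), substr(s, 5, 8), substr(s, 9, 12),
                substr(s, 13, 20), substr(s, 21, 28))
    v <- suppressWarnings(as.numeric(fields))
    if (anyNA(v)) stopf("read_hkl: malformed line %d (expected 3I4,2F8.2)", ln)
    if (all(v[1:3] == 0)) break
    out[[length(out) + 1L]] <- v
  }
  if (!length(out)) stopf("read_hkl: no reflections before terminator")
  m <- do.call(rbind, out)
  can <- canonical_hkl(m[, 1:3, drop = FALSE])
  df <- data.frame(h = can$hkl[, 1], k = can$hkl[, 2], l = can$hkl[, 3],
                   F_obs = m[, 4], sigma = m[, 5])
  key <- hkl_key(can$hkl)
  if (anyDuplicated(key)) {
    warnf("read_hkl: %d equivalent record(s) merged", sum(duplicated(key)))
    w <- ifelse(df$sigma > 0, 1 / df$sigma^2, 1)
    agg <- function(v, wt) tapply(v * wt, key, sum) / tapply(wt, key, sum)
    fo <- agg(df$F_obs, w)
    sg <- sqrt(1 / tapply(w, key, sum)) * (tapply(df$sigma, key, max) > 0)
    first <- !duplicated(key)
    df <- df[first, ]
    df$F_obs <- as.numeric(fo[hkl_key(as.matrix(df[, 1:3]))])
    df$sigma <- as.numeric(sg[hkl_key(as.matrix(df[, 1:3]))])
  }
  df
}

#' Write a seed-phase list to TSV
#'
#' @param seed A `phase_seed`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_seed_tsv <- function(seed, path) {
  df <- data.frame(h = seed$hkl[, 1], k = seed$hkl[, 2], l = seed$hkl[, 3],
                   phi_deg = round(deg(seed$phi)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

RUN_CONFIG_DEFAULTS <- list(
  res_limit = 0.9,
  cycles = 30,
  keep_fraction = 0.025,
  lock_cycles = 15,
  prior_scale = 1,
  threshold = 1.2,
  n_trials = 20,
  flip_fraction = 0.1,
  noise_fraction = 0,
  completeness = 1,
  vol_range = c(1000, 3500),
  n_asym_range = c(10, 55),
  min_dist = 1.5,
  pseudo_fraction = 0,
  auto_res_switch = 1.4,
  rng_seed = 1
)

#' Assemble a run configuration
#'
#' All tunables of the pipeline with their defaults; unknown keys are
#' rejected so configurations stay self-documenting.
#'
#' @param ... Overrides of the default values.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  over <- list(...)
  bad <- setdiff(names(over), names(RUN_CONFIG_DEFAULTS))
  if (length(bad)) stopf("run_config: unknown key(s): %s", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(RUN_CONFIG_DEFAULTS, over)
  structure(cfg, class = "run_config")
}

cli_usage <- function() {
  paste(
    "usage: phaseseed <command> [options]",
    "commands:",
    "  simulate --n <int> --seed <int> --out <dir> [--res <A>]",
    "  seed     --cif <file> --hkl <file> --provider <true|random|noisy> [--flip-fraction <f>] [--seed <int>] --out <tsv>",
    "  dm       --cif <file> [--trials <int>] [--seed-file <tsv>] [--prior-scale <f>] [--seed <int>] --out <json>",
    "  solve    --cif <file> [--path <A|B|C|auto>] [--provider <p>] [--seed-file <tsv>] [--cutoff <A>] [--seed <int>] --out <json>",
    "  bench    --n <int> [--seed <int>] [--providers <csv>] --out <json>",
    "  evaluate --records <csv> --out <json>",
    sep = "\n")
}

parse_args <- function(argv) {
  opts <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stopf("unexpected argument: %s", a)
    key <- substring(a, 3)
    if (i == length(argv) || startsWith(argv[i + 1L], "--"))
      stopf("missing value for --%s", key)
    opts[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  opts
}

opt_or <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else opts[[key]]
}

cli_report <- function(out, payload, cfg) {
  payload$config <- unclass(cfg)
  payload$package_version <- as.character(utils::packageVersion("phaseseed"))
  jsonlite::write_json(payload, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
}

cli_load_rs <- function(opts, cfg) {
  st <- read_cif(opts$cif)
  if (!is.null(opts$hkl)) {
    obs <- read_hkl(opts$hkl)
    rs <- make_reflections(st, as.numeric(opt_or(opts, "res", cfg$res_limit)))
    m <- match(hkl_key(as.matrix(obs[, 1:3])),
               hkl_key(as.matrix(rs$refl[, c("h", "k", "l")])))
    keep <- !is.na(m)
    rs$refl <- rs$refl[m[keep], ]
    rs$refl$F_obs <- obs$F_obs[keep]
    rs$refl$sigma <- obs$sigma[keep]
    rs <- normalize_reflections(rs)
  } else {
    rs <- make_reflections(st, as.numeric(opt_or(opts, "res", cfg$res_limit)))
  }
  list(st = st, rs = rs)
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `phaseseed` script (subcommands `simulate`,
#' `seed`, `dm`, `solve`, `bench`, `evaluate`). Every stochastic path takes a
#' `--seed` integer and the full configuration is echoed into every JSON
#' report, so any result can be re-derived from its report alone.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit status (0 on success).
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  res <- tryCatch({
    if (!length(argv)) { message(cli_usage()); return(1L) }
    cmd <- argv[1]
    opts <- parse_args(argv[-1])
    rng <- as.integer(opt_or(opts, "seed", 1))
    cfg <- run_config(rng_seed = rng)
    if (cmd == "simulate") {
      n <- as.integer(opts$n)
      dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
      sts <- generate_cohort(n, rng_seed = rng)
      for (i in seq_len(n)) {
        rs <- make_reflections(sts[[i]], as.numeric(opt_or(opts, "res", cfg$res_limit)))
        write_cif(sts[[i]], file.path(opts$out, sprintf("structure_%03d.cif", i)))
        write_hkl(rs, file.path(opts$out, sprintf("structure_%03d.hkl", i)))
      }
      message(sprintf("wrote %d structures to %s", n, opts$out))
    } else if (cmd == "seed") {
      x <- cli_load_rs(opts, cfg)
      seed <- make_seed(x$rs, opt_or(opts, "provider", "true"),
                        flip_fraction = as.numeric(opt_or(opts, "flip-fraction", cfg$flip_fraction)),
                        rng_seed = rng)
      write_seed_tsv(seed, opts$out)
      message(sprintf("wrote %d seed phases to %s", length(seed$phi), opts$out))
    } else if (cmd == "dm") {
      x <- cli_load_rs(opts, cfg)
      seed <- if (!is.null(opts[["seed-file"]])) import_seed(opts[["seed-file"]], x$rs)
      ms <- multisolution(x$rs, n_trials = as.integer(opt_or(opts, "trials", cfg$n_trials)),
                          seed = seed, rng_seed = rng,
                          prior_scale = as.numeric(opt_or(opts, "prior-scale", cfg$prior_scale)),
                          threshold = as.numeric(opt_or(opts, "threshold", cfg$threshold)))
      cli_report(opts$out, list(trials = ms$trials, best = ms$best), cfg)
    } else if (cmd == "solve") {
      x <- cli_load_rs(opts, cfg)
      if (!is.null(opts$cutoff)) x$rs <- apply_resolution_cutoff(x$rs, as.numeric(opts$cutoff))
      seed <- if (!is.null(opts[["seed-file"]])) import_seed(opts[["seed-file"]], x$rs)
      else make_seed(x$rs, opt_or(opts, "provider", "true"), rng_seed = rng)
      pth <- opt_or(opts, "path", "A")
      strategy <- c(A = "seed", B = "dm", C = "dm_seed", auto = "auto")[[pth]]
      sol <- solve_structure(x$rs, seed, strategy = strategy, rng_seed = rng)
      cli_report(opts$out, list(path = sol$path, MPE_final = sol$MPE_final,
                                CORR_final = sol$CORR_final, R_f = sol$R_f,
                                converged = sol$converged, trace = sol$trace), cfg)
    } else if (cmd == "bench") {
      n <- as.integer(opts$n)
      provs <- strsplit(opt_or(opts, "providers", "true,noisy,random"), ",")[[1]]
      sts <- generate_cohort(n, rng_seed = rng, vol_range = c(1000, 2000),
                             n_asym_range = c(10, 25))
      recs <- run_cohort(sts, providers = provs, rng_seed = rng)
      cl <- cluster_solved(recs, rng_seed = rng)
      recs$solved <- cl$solved
      effs <- lapply(provs, function(pv) {
        sel <- startsWith(recs$provider, pv)
        efficiency(sum(recs$solved[sel]), sum(sel))
      })
      names(effs) <- provs
      cli_report(opts$out, list(records = recs, efficiency = effs,
                                mean_silhouette = cl$mean_silhouette), cfg)
    } else if (cmd == "evaluate") {
      recs <- utils::read.csv(opts$records, stringsAsFactors = FALSE)
      cl <- cluster_solved(recs)
      th <- class_thresholds(recs, cl$solved)
      rf <- rf_classify(recs, th$class1, rng_seed = rng)
      cli_report(opts$out, list(
        mean_silhouette = cl$mean_silhouette,
        efficiency = efficiency(sum(cl$solved), length(cl$solved)),
        Q1 = th$Q1, Q3 = th$Q3, auc = rf$auc, threshold = rf$threshold,
        confusion = as.data.frame(rf$confusion),
        importance = as.list(rf$importance)), cfg)
    } else {
      message(cli_usage())
      return(1L)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  res
}
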