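# Configuration, trajectory and sidecar I/O. All formats are plain text:
# YAML config, extended-XYZ trajectories, CSV sidecars, BED-like tracks.

config_defaults <- function() {
  list(
    seed = 1L,
    zeta = 1,
    output = NULL,
    genome = list(
      karyotype = "human",        # "human", "tutorial", or path to TSV
      track = NULL,               # path to BED-like track; NULL = synthesize
      synthesis = list(
        constraints = list(chr12 = 30.92, chr18 = 18.64, chr19 = 62.03,
                           chr20 = 29.71),
        default_mean = 27,
        sdlog = 1)),
    activity = list(
      mode = "inhomogeneous",
      active_fraction = 0.05,
      T_a = 20),
    forcefield = list(
      k_bond = 5, r0 = 1, V0 = 2, sigma = 1, k_wall = 50,
      loop_k_multiplier = 10, eps_ne = 50, lambda_ne = 1, r_cut = 3),
    geometry = list(kind = "sphere", R0 = 10, aspect = 1),
    loops = list(preset = NULL, p_loop = NULL),
    schedule = list(dt = 0.01, n_steps = 100000L, n_burnin = NULL,
                    sample_every = 1000L),
    ne = list(enabled = FALSE,
              switch = list(n_init = 4L, times_steps = NULL)))
}

# Merge user values over the default tree; unknown keys (at any level of
# the schema) are collected and reported together.
merge_config <- function(defaults, user, path = character()) {
  bad <- character()
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      bad <- c(bad, full)
      next
    }
    # leaves that are free-form maps are replaced wholesale
    free <- full %in% c("genome.synthesis.constraints")
    if (is.list(defaults[[key]]) && !free) {
      sub <- merge_config(defaults[[key]],
                          if (is.list(user[[key]])) user[[key]] else
                            stop(sprintf("config key '%s' must be a mapping", full)),
                          c(path, key))
      defaults[[key]] <- sub$value
      bad <- c(bad, sub$bad)
    } else {
      defaults[key] <- list(user[[key]])  # keep explicit nulls as NULL keys
    }
  }
  list(value = defaults, bad = bad)
}

validate_config <- function(user) {
  m <- merge_config(config_defaults(), user)
  if (length(m$bad)) {
    stop(sprintf("unknown config key(s): %s", paste(m$bad, collapse = ", ")))
  }
  cfg <- m$value
  if (is.null(cfg$schedule$n_burnin)) {
    cfg$schedule$n_burnin <- floor(cfg$schedule$n_steps / 10)
  }
  # materialize and type-check through the constructors
  invisible(force_field(cfg$forcefield$k_bond, cfg$forcefield$r0,
                        cfg$forcefield$V0, cfg$forcefield$sigma,
                        cfg$forcefield$k_wall,
                        cfg$forcefield$loop_k_multiplier,
                        cfg$forcefield$eps_ne, cfg$forcefield$lambda_ne,
                        cfg$forcefield$r_cut))
  if (!cfg$geometry$kind %in% c("sphere", "ellipsoid")) {
    stop("geometry.kind must be 'sphere' or 'ellipsoid'")
  }
  if (!cfg$activity$mode %in% c("inhomogeneous", "homogeneous",
                                "equilibrium")) {
    stop("activity.mode must be inhomogeneous, homogeneous or equilibrium")
  }
  if (!is.null(cfg$loops$preset) &&
      !cfg$loops$preset %in% names(loop_presets())) {
    stop("loops.preset must be one of low, mid, high")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Default run configuration
#'
#' The fully materialized default `run_config`: the canonical schema with
#' every default value explicit. Useful as a template to modify.
#'
#' @return A `run_config`.
#' @export
default_config <- function() validate_config(list())

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, validates it against the canonical schema
#' (unknown keys are rejected, all of them named) and materializes every
#' default, so the returned object is fully explicit and can be echoed
#' verbatim next to the outputs it produced.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @seealso [write_config()] for the echo; [run_simulation()] to execute.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_config(user)
}

#' @rdname load_config
#' @param config a `run_config` (or plain list, validated first).
#' @export
write_config <- function(config, path) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Assemble the model components described by a configuration
#'
#' Builds the karyotype, gene-density track, monomer table (with activity
#' assigned), force field, geometry, loop set and schedule from a validated
#' `run_config`, without running any dynamics.
#'
#' @param config a `run_config`.
#' @param seed overrides `config$seed` when given.
#' @return List with `table`, `ff`, `geom`, `loops`, `sch`, `config`.
#' @export
build_system <- function(config, seed = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  kar <- switch(config$genome$karyotype,
                human = human_karyotype(),
                tutorial = tutorial_karyotype(),
                load_karyotype(config$genome$karyotype))
  track <- if (is.null(config$genome$track)) {
    syn <- config$genome$synthesis
    cons <- syn$constraints[names(syn$constraints) %in% kar$name]
    synthesize_gene_track(kar, constraints = cons,
                          default_mean = syn$default_mean, sdlog = syn$sdlog,
                          seed = sub_seed(config$seed, "genome"))
  } else {
    load_gene_track(config$genome$track)
  }
  table <- build_monomer_table(kar, track)
  table <- assign_activity(table, config$activity$mode,
                           config$activity$active_fraction,
                           config$activity$T_a)
  ff <- do.call(force_field, config$forcefield)
  geom <- geometry(config$geometry$kind, R0 = config$geometry$R0,
                   aspect = config$geometry$aspect)
  p_loop <- if (!is.null(config$loops$p_loop)) {
    config$loops$p_loop
  } else if (!is.null(config$loops$preset)) {
    loop_presets()[[config$loops$preset]]
  }
  loops <- if (!is.null(p_loop)) {
    generate_loops(table, p_loop, ff, seed = sub_seed(config$seed, "loops"))
  }
  sch <- schedule(config$schedule$dt, config$schedule$n_steps,
                  config$schedule$n_burnin, config$schedule$sample_every,
                  seed = config$seed)
  list(table = table, ff = ff, geom = geom, loops = loops, sch = sch,
       config = config)
}

#' Run a simulation from a configuration
#'
#' End-to-end orchestration: [build_system()], [simulate_chromosomes()],
#' and -- when an output directory is configured -- a self-describing output
#' bundle (config echo, trajectory, monomer-table and loop-set sidecars).
#' Deterministic given (config, seed).
#'
#' @param config a `run_config` (see [load_config()]).
#' @param seed overrides `config$seed`.
#' @param out_dir overrides `config$output`.
#' @return An `actseg_run` (invisibly carries the echoed config as
#'   `$config`).
#' @export
run_simulation <- function(config, seed = NULL, out_dir = NULL) {
  sys <- build_system(config, seed)
  if (is.null(out_dir)) out_dir <- sys$config$output
  run <- simulate_chromosomes(sys$table, sys$ff, sys$geom, sys$sch,
                              loops = sys$loops,
                              ne_on = isTRUE(sys$config$ne$enabled),
                              zeta = sys$config$zeta)
  run$config <- sys$config
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(sys$config, file.path(out_dir, "config.yaml"))
    write_trajectory(run, file.path(out_dir, "trajectory.xyz"))
    write_monomer_table(sys$table, file.path(out_dir, "monomers.csv"))
    if (!is.null(sys$loops)) {
      write_loops(sys$loops, file.path(out_dir, "loops.csv"))
    }
    utils::write.csv(data.frame(time = run$times, energy = run$energy),
                     file.path(out_dir, "energy.csv"), row.names = FALSE)
  }
  run
}

#' Load a karyotype from a TSV file
#'
#' Columns: name, length_mb, copies (tab-separated, `#` comments).
#'
#' @param path file path.
#' @return A `karyotype`.
#' @export
load_karyotype <- function(path) {
  raw <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("name", "length_mb", "copies"))
  karyotype(raw$name, raw$length_mb, raw$copies)
}

#' Write / read the monomer table sidecar
#'
#' CSV with columns id, chrom, copy, chain_index, gene_content,
#' activity_class, T_eff -- the canonical per-monomer sidecar written next
#' to every trajectory.
#'
#' @param table a `monomer_table`.
#' @param path file path.
#' @return `write_monomer_table`: `path` invisibly; `read_monomer_table`:
#'   a `monomer_table`.
#' @export
write_monomer_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_monomer_table
#' @export
read_monomer_table <- function(path) {
  out <- utils::read.csv(path, colClasses = c("integer", "character",
                                              "integer", "integer",
                                              "numeric", "character",
                                              "numeric"))
  class(out) <- c("monomer_table", "data.frame")
  out
}

#' Write a trajectory as extended-XYZ text
#'
#' One block per frame: the monomer count, a comment line carrying the time
#' and the confinement geometry, then one line per monomer with the
#' chromosome label, the three coordinates (full double precision) and the
#' monomer id.
#'
#' @param x an `actseg_run`, or an n x 3 x F array.
#' @param path output path.
#' @param table,geom,times required when `x` is a raw array.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(x, path, table = NULL, geom = NULL,
                             times = NULL) {
  if (inherits(x, "actseg_run")) {
    table <- x$table; geom <- x$geom; times <- x$times; x <- x$frames
  }
  if (is.matrix(x)) x <- array(x, c(nrow(x), 3, 1))
  nf <- dim(x)[3]
  n <- dim(x)[1]
  if (n != nrow(table)) stop("frame width does not match the monomer table")
  if (is.null(times)) times <- rep(NA_real_, nf)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("time=%.17g kind=%s R0=%.17g a=%.17g c=%.17g",
                       times[f], geom$kind, geom$R0, geom$axes[[1]],
                       geom$axes[[3]]), con)
    writeLines(sprintf("%s %.17g %.17g %.17g %d", table$chrom,
                       x[, 1, f], x[, 2, f], x[, 3, f], table$id), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Inverse of [write_trajectory()]. Coordinates round-trip to full double
#' precision; the geometry and frame times are recovered from the comment
#' lines.
#'
#' @param path trajectory path.
#' @return List with `frames` (n x 3 x F), `times`, `labels`, `ids`,
#'   `geom`.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list()
  times <- numeric()
  labels <- NULL
  ids <- NULL
  geom <- NULL
  f <- 0L
  while (pos <= length(lines)) {
    f <- f + 1L
    n <- suppressWarnings(as.integer(lines[pos]))
    if (is.na(n)) stop(sprintf("malformed frame header at frame %d", f))
    if (pos + 1L + n > length(lines)) {
      stop(sprintf("truncated trajectory at frame %d", f))
    }
    hdr <- lines[pos + 1L]
    kv <- regmatches(hdr, gregexpr("[A-Za-z0-9_]+=[^ ]+", hdr))[[1]]
    kvl <- stats::setNames(lapply(strsplit(kv, "="), `[`, 2),
                           vapply(strsplit(kv, "="), `[`, "", 1))
    times[f] <- as.numeric(kvl[["time"]])
    if (is.null(geom)) {
      kind <- kvl[["kind"]]
      if (kind == "sphere") {
        geom <- geometry("sphere", R0 = as.numeric(kvl[["R0"]]))
      } else {
        a <- as.numeric(kvl[["a"]]); cc <- as.numeric(kvl[["c"]])
        geom <- geometry("ellipsoid", axes = c(a, a, cc))
      }
    }
    body <- lines[pos + 1L + seq_len(n)]
    parts <- strsplit(body, " ", fixed = TRUE)
    if (any(lengths(parts) != 5L)) {
      stop(sprintf("malformed monomer line in frame %d", f))
    }
    m <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), ncol = 3,
                byrow = TRUE)
    if (is.null(labels)) {
      labels <- vapply(parts, `[`, "", 1)
      ids <- as.integer(vapply(parts, `[`, "", 5))
    }
    frames[[f]] <- m
    pos <- pos + 2L + n
  }
  arr <- array(unlist(frames), c(nrow(frames[[1]]), 3, length(frames)))
  list(frames = arr, times = times, labels = labels, ids = ids, geom = geom)
}
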