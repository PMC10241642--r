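## File formats and pipeline assembly.  Packings travel as extended-XYZ
## (count line, key=value comment line with the cubic box edge and
## periodic flags, then "x y z diameter_nm" rows); spectra and curves as
## CSV with a leading wavelength_nm column.  All formats are plain text
## and round-trip at full double precision.

#' Write / read a particle configuration as extended XYZ
#'
#' @param config A `particle_configuration`.
#' @param path File path.
#' @return `read_packing()` returns a `particle_configuration`;
#'   `write_packing()` returns `path` invisibly.
#' @export
write_packing <- function(config, path) {
  n <- nrow(config$positions)
  prov <- if (!is.null(config$provenance))
    jsonlite::toJSON(config$provenance, auto_unbox = TRUE, digits = NA)
  else NULL
  meta <- sprintf('box_edge_nm=%.17g periodic=TTT properties=x:y:z:diameter_nm%s',
                  config$box,
                  if (is.null(prov)) "" else paste0(' provenance=', prov))
  rows <- sprintf("%.17g %.17g %.17g %.17g",
                  config$positions[, 1], config$positions[, 2],
                  config$positions[, 3], config$diameters)
  writeLines(c(as.character(n), meta, rows), path)
  invisible(path)
}

#' @rdname write_packing
#' @export
read_packing <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed packing file: fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed packing file: line 1 is not a particle count")
  meta <- lines[2]
  mbox <- regmatches(meta, regexpr("box_edge_nm=[^ ]+", meta))
  if (!length(mbox)) stop("malformed packing file: line 2 lacks box_edge_nm")
  box <- as.numeric(sub("box_edge_nm=", "", mbox))
  if (length(lines) - 2L != n)
    stop(sprintf("particle count mismatch: header says %d, found %d rows (line %d)",
                 n, length(lines) - 2L, min(length(lines), n + 3L)))
  vals <- lapply(seq_len(n), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 2L]), "[ \t]+")[[1]]))
    if (length(v) < 4L || any(is.na(v[1:4])))
      stop(sprintf("parse error at line %d: need 'x y z diameter_nm'", i + 2L))
    v[1:4]
  })
  m <- do.call(rbind, vals)
  prov <- NULL
  mprov <- regmatches(meta, regexpr("provenance=\\{.*\\}", meta))
  if (length(mprov))
    prov <- jsonlite::fromJSON(sub("provenance=", "", mprov))
  structure(list(box = box, positions = m[, 1:3, drop = FALSE],
                 diameters = m[, 4], provenance = prov),
            class = "particle_configuration")
}

#' Write / read spectra and reflectance curves as CSV
#'
#' First column `wavelength_nm`, remaining columns named channels
#' (e.g. `Q_sca`, `R`, `TE2`).  Wavelength monotonicity is enforced on
#' read.
#'
#' @param x A `scattering_spectrum`, `transport_result`, or data.frame
#'   with a `wavelength_nm` column.
#' @param path File path.
#' @export
write_spectrum <- function(x, path) {
  df <- if (is.data.frame(x)) {
    x
  } else if (inherits(x, "scattering_spectrum")) {
    d <- data.frame(wavelength_nm = x$wavelengths, Q_sca = x$Q_sca)
    if (!is.null(x$per_multipole)) d <- cbind(d, as.data.frame(x$per_multipole))
    d
  } else if (inherits(x, "transport_result")) {
    data.frame(wavelength_nm = x$wavelengths, R = x$R,
               l_s = x$l_s, l_t = x$l_t)
  } else stop("unsupported object for write_spectrum()")
  if (names(df)[1] != "wavelength_nm")
    stop("first column must be 'wavelength_nm'")
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "wavelength_nm")
    stop("spectrum CSV must start with a 'wavelength_nm' column")
  if (any(diff(df$wavelength_nm) <= 0))
    stop("wavelength grid in file is not strictly increasing")
  df
}

#' Run the canonical analysis pipeline
#'
#' End-to-end desk-scale flow: generate a packing, measure its structure,
#' compute the slab reflectance with the coordinate structure factor, and
#' run the fill-fraction sweep; artifacts are written to `out_dir` with a
#' provenance manifest (inputs, seed, file hashes).
#'
#' @param config List with entries `seed`, `out_dir` and optional stage
#'   parameter lists `packing` (passed to [glass_recipe()]), `reflectance`
#'   (`L`, `wavelengths`), `sweep` (`phi_grid`, `sigma1`); set a stage to
#'   `FALSE` to skip it.
#' @return Invisibly, a list of artifact paths plus the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) stop("config must name a seed")
  out <- config$out_dir %||% tempfile("spherulite_run_")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  log_msg <- function(...) message("[spherulite] ", sprintf(...))

  pk_args <- config$packing %||% list()
  pk_args$seed <- config$seed
  recipe <- do.call(glass_recipe, pk_args)
  log_msg("packing: N = %d, fill = %.2f, steps = %d",
          recipe$n_particles, recipe$target_fill, recipe$quench_steps)
  cfg <- generate_packing(recipe)
  paths$packing <- file.path(out, "packing.xyz")
  write_packing(cfg, paths$packing)

  log_msg("structure: g(r) and S(q)")
  sk <- structure_factor_from_config(cfg)
  paths$sq <- file.path(out, "structure_factor.csv")
  utils::write.csv(data.frame(q_invnm = sk$q, S = sk$S), paths$sq,
                   row.names = FALSE)
  gr <- radial_distribution(cfg)
  paths$gr <- file.path(out, "radial_distribution.csv")
  utils::write.csv(data.frame(r_nm = gr$r, g = gr$g), paths$gr,
                   row.names = FALSE)

  rf_args <- config$reflectance %||% list()
  sq_fun <- stats::approxfun(sk$q, sk$S, yleft = sk$S[1],
                             yright = 1, rule = 2)
  particle <- rf_args$particle %||%
    anisotropic_sphere(recipe$mu1, 1.96, 1.40)
  asm <- assembly_spec(particle, measure_filling_fraction(cfg),
                       sigma1 = recipe$sigma1, sq = sq_fun)
  log_msg("reflectance: L = %g nm", rf_args$L %||% 5000)
  tr <- reflectance_spectrum(asm, L = rf_args$L %||% 5000,
                             wavelengths = rf_args$wavelengths %||%
                               seq(400, 700, by = 5))
  paths$reflectance <- file.path(out, "reflectance.csv")
  write_spectrum(tr, paths$reflectance)

  if (!isFALSE(config$sweep)) {
    sw_args <- config$sweep %||% list()
    log_msg("fill-fraction sweep")
    sw <- fill_fraction_sweep(
      particles = list(iso_1.96 = anisotropic_sphere(recipe$mu1, 1.96),
                       iso_1.74 = anisotropic_sphere(recipe$mu1, 1.74),
                       birefringent = anisotropic_sphere(recipe$mu1, 1.96, 1.40)),
      phi_grid = sw_args$phi_grid %||% seq(0.05, 0.70, by = 0.05),
      L = sw_args$L %||% 5000,
      sigma1 = sw_args$sigma1 %||% 0)
    paths$sweep <- file.path(out, "fill_sweep.csv")
    utils::write.csv(sw$curve, paths$sweep, row.names = FALSE)
  }

  manifest <- list(
    seed = config$seed,
    recipe = unclass(recipe),
    files = lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  paths$manifest_json <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_msg("done: %s", out)
  invisible(c(paths, list(manifest = manifest, out_dir = out)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
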