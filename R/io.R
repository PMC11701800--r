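# Configuration loading/validation and result writers (CSV with a metadata
# comment block, legacy ASCII VTK rectilinear grids, JSON run manifest).

# schema: section -> field -> list(type, positive?, quantity class)
config_schema <- function() {
  num <- function(pos = TRUE) list(kind = "number", positive = pos)
  cnt <- list(kind = "count")
  lgl <- list(kind = "logical")
  vec <- list(kind = "numeric_vector")
  chr <- list(kind = "string")
  list(
    chamber = list(length_x = num(), width_y = num(), height_z = num(),
                   inlet_diameter = num(), inlet_height = num(),
                   half_model = lgl),
    microstructure = list(footprint_x = num(), footprint_y = num(),
                          height = num(), pore_x = num(), pore_y = num(),
                          pore_z = num(), beam_axial = num(),
                          beam_lateral = num()),
    array = list(n_rows = cnt, n_cols = cnt, pitch_x = num(),
                 lateral_offset = num(FALSE)),
    grid = list(dx = num(), dy = num(), dz_fine = num(), fine_height = num(),
                growth = num()),
    fluid = list(mu = num(), rho = num(), temperature = num(FALSE)),
    oxygen = list(D = num(), C0 = num(), Vmax = num(), Km = num()),
    loading = list(n_total = cnt, n_array = cnt, n_flat = cnt),
    conversion = list(percent_atm_inlet = num(), hypoxia_percent = num(),
                      normoxia_percent = num()),
    ranges = list(velocity_min = num(), velocity_max = num(),
                  velocity_max_broad = num(), wss_min = num(),
                  wss_max = num()),
    sweep = list(rates_uL_min = vec, rule = chr),
    unit_cell = list(spacing = num(), clearance = num())
  )
}

#' Load and validate a configuration file
#'
#' Reads a YAML configuration, validates it against the schema (unknown
#' sections or keys are rejected; all violations are reported at once),
#' normalises unit-suffixed strings (`"500 um"`, `"5 uL/min"`) to SI and
#' fills unspecified fields from [default_config()].
#'
#' @param path path to a YAML file.
#' @return a validated `perfusim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  schema <- config_schema()
  cfg <- default_config()
  errs <- character(0)
  for (sec in names(raw)) {
    if (!sec %in% names(schema)) {
      errs <- c(errs, paste0("unknown section [", sec, "]"))
      next
    }
    for (key in names(raw[[sec]])) {
      if (!key %in% names(schema[[sec]])) {
        errs <- c(errs, paste0("unknown key ", sec, ".", key))
        next
      }
      spec <- schema[[sec]][[key]]
      val <- raw[[sec]][[key]]
      parsed <- tryCatch(switch(spec$kind,
        number = parse_quantity(val, paste0(sec, ".", key)),
        count = {
          v <- as.numeric(val)
          if (is.na(v) || v < 0 || v != round(v)) stop("must be a count >= 0")
          as.integer(v)
        },
        logical = {
          if (!is.logical(val)) stop("must be true/false")
          val
        },
        numeric_vector = {
          v <- vapply(val, parse_quantity, numeric(1))
          if (length(v) == 0) stop("must be a non-empty numeric list")
          v
        },
        string = as.character(val)
      ), error = function(e) e)
      if (inherits(parsed, "error")) {
        errs <- c(errs, paste0(sec, ".", key, ": ", conditionMessage(parsed)))
      } else {
        if (!is.null(spec$positive) && isTRUE(spec$positive) &&
            is.numeric(parsed) && any(parsed <= 0)) {
          errs <- c(errs, paste0(sec, ".", key, ": must be > 0"))
        } else {
          cfg[[sec]][[key]] <- parsed
        }
      }
    }
  }
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  if (cfg$loading$n_array + cfg$loading$n_flat != cfg$loading$n_total)
    stop("invalid configuration:\n  - loading: n_array + n_flat must equal n_total")
  class(cfg) <- "perfusim_config"
  cfg
}

#' Path of the bundled reference configuration file
#' @return file path of the YAML shipped with the package.
#' @export
reference_config_path <- function() {
  system.file("extdata", "moab_default.yaml", package = "perfusim",
              mustWork = TRUE)
}

# CSV with '#' metadata comment block
write_csv_meta <- function(df, path, meta = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a result CSV written by [write_results()]
#' @param path CSV path.
#' @return data frame (metadata comment lines skipped).
#' @export
read_results_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write a legacy ASCII VTK rectilinear grid with cell data
#'
#' @param grid a `labeled_grid`.
#' @param celldata named list of cell-centred arrays (`nx x ny x nz`);
#'   integer arrays are written as int scalars, others as double.
#' @param path output `.vtk` path.
#' @param title dataset title line.
#' @return the path, invisibly.
#' @export
write_vtk_rectilinear <- function(grid, celldata, path,
                                  title = "perfusim field export") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl(title)
  wl("ASCII")
  wl("DATASET RECTILINEAR_GRID")
  wl("DIMENSIONS ", grid$nx + 1L, " ", grid$ny + 1L, " ", grid$nz + 1L)
  wcoords <- function(lbl, v) {
    wl(lbl, " ", length(v), " double")
    wl(paste(format(v, digits = 9, scientific = TRUE, trim = TRUE),
             collapse = " "))
  }
  wcoords("X_COORDINATES", grid$xf)
  wcoords("Y_COORDINATES", grid$yf)
  wcoords("Z_COORDINATES", grid$zf)
  ncell <- grid$nx * grid$ny * grid$nz
  wl("CELL_DATA ", ncell)
  for (nm in names(celldata)) {
    arr <- celldata[[nm]]
    is_int <- is.integer(arr)
    wl("SCALARS ", nm, if (is_int) " int 1" else " double 1")
    wl("LOOKUP_TABLE default")
    vals <- as.vector(arr) # R column-major == VTK x-fastest ordering
    if (is_int) {
      writeLines(paste(vals, collapse = " "), con)
    } else {
      writeLines(paste(format(vals, digits = 9, scientific = TRUE,
                              trim = TRUE), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Run manifest
#'
#' @param cfg configuration used.
#' @param seed integer seed recorded for the run.
#' @param stages named list of per-stage metadata (residuals, iterations).
#' @return manifest list (also has a JSON representation via
#'   [write_results()]).
#' @export
run_manifest <- function(cfg, seed = NA_integer_, stages = list()) {
  list(package = "perfusim",
       version = as.character(utils::packageVersion("perfusim")),
       config_hash = config_hash(cfg), seed = seed, stages = stages)
}

#' Write sweep/operating-point results to a directory
#'
#' Writes the report tables as CSV (RFC-4180 with a `#` metadata comment
#' block), the region-label grid and (optionally) field VTKs, and a JSON
#' manifest. Output is deterministic: re-running with the same configuration
#' reproduces identical files.
#'
#' @param sweep a `sweep_result`.
#' @param out_dir output directory (created if missing).
#' @param seed seed recorded in the manifest.
#' @param fields write VTK field exports (flow + oxygen of the recommended
#'   rate).
#' @return invisible character vector of files written.
#' @export
write_results <- function(sweep, out_dir, seed = NA_integer_,
                          fields = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- generate_report_tables(sweep)
  h <- config_hash(sweep$cfg)
  files <- character(0)
  for (nm in names(tabs)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    meta <- c(paste0("config ", h),
              paste0("rates_uL_min ",
                     paste(sweep$table$Q_uL_min, collapse = ",")),
              paste0("grid ", sweep$base$grid$nx, "x", sweep$base$grid$ny,
                     "x", sweep$base$grid$nz))
    write_csv_meta(tabs[[nm]], f, meta)
    files <- c(files, f)
  }
  rec <- sweep$recommendation
  st <- list(flow = sweep$base$flow_ref$residuals,
             unit_cell = sweep$base$cell_sol$residuals)
  if (fields) {
    idx <- if (rec$feasible) which(sweep$table$Q_uL_min == rec$Q_uL_min)[1] else 1L
    p <- sweep$points[[idx]]
    cc <- collocate_velocity(scale_flow(sweep$base$flow_ref, p$Q))
    f <- file.path(out_dir, "fields.vtk")
    write_vtk_rectilinear(sweep$base$grid,
                          list(region = sweep$base$grid$lab,
                               u_x = cc$u, u_y = cc$v, u_z = cc$w,
                               oxygen = p$oxygen$C),
                          f)
    files <- c(files, f)
    st$oxygen <- list(iterations = p$oxygen$iterations,
                      final_update = p$oxygen$final_update)
  }
  mf <- file.path(out_dir, "manifest.json")
  man <- run_manifest(sweep$cfg, seed = seed, stages = st)
  man$recommended_uL_min <- rec$Q_uL_min
  jsonlite::write_json(man, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, mf)
  invisible(files)
}
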