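# Study orchestration: configuration, single-case runs, and the full
# cohort-level parametric study (DoE -> FE solves -> response surface ->
# local sensitivities -> group statistics).

#' Default study configuration
#'
#' Returns the fully populated configuration list used by [run_case()] and
#' [run_study()]; any subset of fields can be overridden via a YAML/JSON file
#' or a nested list.  The baseline osteotomy is expressed as fractions of the
#' per-case skull dimensions so that every synthetic patient receives an
#' equivalent as-operated configuration.
#'
#' @param overrides nested list (or path to a YAML file) overriding defaults.
#' @return configuration list of class `study_config`.
#' @export
study_config <- function(overrides = NULL) {
  cfg <- list(
    cohort = list(n_t2 = 6, n_l2 = 6, n_tl4 = 6,
                  base_spec = list(length_ap = 170, width_ml = 140,
                                   height_cc = 100, thickness = 3,
                                   foramen_radius = 15, mesh_edge_target = 6,
                                   bump_amplitude = 1.5),
                  variability = 0.05, seed = 1L, growth_factor = 1),
    material = list(E = 1300, nu = 0.22,
                    prony = list(list(g = 0.9, tau = 7))),
    osteotomy = list(l_frac = 0.10, h_frac = 0.25, alpha = 55, kerf = 2),
    springs = list(model = "S12", s_t = 25, s_l = 30),
    doe = list(seed = 1L, n_t2 = NULL, n_l2 = NULL, n_tl4 = NULL,
               max_sweeps = 200L),
    solver = list(duration = 150, n_steps = 5, tol = 1e-4, max_iter = 60),
    output = list(dir = NULL)
  )
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  if (!is.null(overrides)) cfg <- modifyList(cfg, overrides)
  validate_config(cfg)
  structure(cfg, class = "study_config")
}

validate_config <- function(cfg) {
  req <- function(cond, msg) if (!isTRUE(cond)) stop("config error: ", msg, call. = FALSE)
  req(all(c("cohort", "material", "osteotomy", "springs", "solver") %in% names(cfg)),
      "missing top-level block")
  req(is.numeric(cfg$cohort$n_t2) && cfg$cohort$n_t2 >= 0, "cohort$n_t2 must be >= 0")
  req(is.numeric(cfg$cohort$n_l2) && cfg$cohort$n_l2 >= 0, "cohort$n_l2 must be >= 0")
  req(is.numeric(cfg$cohort$n_tl4) && cfg$cohort$n_tl4 >= 0, "cohort$n_tl4 must be >= 0")
  req(!is.null(cfg$springs$model), "springs$model is required (S10/S12/S14)")
  req(cfg$springs$model %in% c("S10", "S12", "S14"),
      sprintf("unknown spring model '%s'", cfg$springs$model))
  req(is.numeric(cfg$material$E) && cfg$material$E > 0, "material$E must be positive")
  req(is.numeric(cfg$solver$duration) && cfg$solver$duration > 0,
      "solver$duration must be positive")
  invisible(TRUE)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = 12)
  unname(tools::md5sum(tmp))
}

cohort_from_config <- function(cfg) {
  bs <- cfg$cohort$base_spec
  base_spec <- skull_spec(length_ap = bs$length_ap, width_ml = bs$width_ml,
                          height_cc = bs$height_cc, thickness = bs$thickness,
                          foramen_radius = bs$foramen_radius,
                          mesh_edge_target = bs$mesh_edge_target,
                          bump_amplitude = bs$bump_amplitude,
                          seed = cfg$cohort$seed)
  generate_cohort(cfg$cohort$n_t2, cfg$cohort$n_l2, cfg$cohort$n_tl4,
                  base_spec, cfg$cohort$variability, cfg$cohort$seed)
}

case_baseline <- function(surface, cfg) {
  ap <- diff(range(surface$vertices[, 1]))
  ht <- max(surface$vertices[, 2])
  params <- osteotomy_params(L = cfg$osteotomy$l_frac * ap,
                             H = cfg$osteotomy$h_frac * ht,
                             alpha = cfg$osteotomy$alpha,
                             kerf = cfg$osteotomy$kerf)
  params
}

material_from_config <- function(cfg) {
  material_model(E = cfg$material$E, nu = cfg$material$nu,
                 prony = cfg$material$prony)
}

solve_one <- function(surface, params, placements, cfg,
                      track_icv = "final") {
  cut <- apply_osteotomy(surface, params)
  cut <- place_springs(cut, placements)
  model <- build_fe_model(cut, material_from_config(cfg))
  res <- solve_expansion(model, duration = cfg$solver$duration,
                         n_steps = cfg$solver$n_steps, tol = cfg$solver$tol,
                         max_iter = cfg$solver$max_iter, track_icv = track_icv)
  list(result = res, model = model, cut = cut)
}

#' Run a single as-operated case
#'
#' Generates (or accepts) one skull, aligns it, applies the baseline
#' osteotomy and spring placements, solves the expansion and reports pre and
#' post ICV.  With an output directory set, the meshes (STL + JSON sidecar),
#' the deformed surface (STL + VTK with displacements) and a JSON report are
#' written; re-running the same configuration reproduces the report
#' byte-for-byte.
#'
#' @param config a [study_config()] (or overrides accepted by it).
#' @param case_id index into the synthetic cohort (or a `skull_surface` to
#'   use directly).
#' @param procedure procedure label used when a surface is supplied.
#' @return list with `icv_pre`, `icv_post`, `gain_pct`, `openings`,
#'   `converged`, `case_id`, `procedure`, `config_hash`.
#' @export
run_case <- function(config = study_config(), case_id = 1L, procedure = NULL) {
  if (!inherits(config, "study_config")) config <- study_config(config)
  if (inherits(case_id, "skull_surface")) {
    surface <- align_to_frame(case_id)$surface
    procedure <- procedure %||% "T2"
    cid <- "custom"
  } else {
    cohort <- cohort_from_config(config)
    if (case_id > length(cohort)) stop("case_id beyond cohort size", call. = FALSE)
    cs <- cohort[[case_id]]
    surface <- align_to_frame(cs$surface)$surface
    if (config$cohort$growth_factor != 1) {
      surface <- scale_for_growth(surface, config$cohort$growth_factor)
    }
    procedure <- procedure %||% cs$procedure
    cid <- cs$case_id
  }
  params <- case_baseline(surface, config)
  placements <- procedure_placements(procedure, s_t = config$springs$s_t,
                                     s_l = config$springs$s_l,
                                     spring_model = config$springs$model)
  sol <- solve_one(surface, params, placements, config, track_icv = "all")
  res <- sol$result
  icv_pre <- res$icv_ml[1]
  icv_post <- res$icv_ml[length(res$icv_ml)]
  out <- list(case_id = cid, procedure = procedure,
              icv_pre = icv_pre, icv_post = icv_post,
              gain_pct = icv_gain(icv_pre, icv_post),
              icv_trajectory = res$icv_ml, time = res$time,
              openings = res$openings[nrow(res$openings), ],
              converged = res$converged,
              config_hash = config_hash(unclass(config)))
  dir <- config$output$dir
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_skull_stl(list(vertices = sol$model$nodes, faces = sol$model$tris),
                    file.path(dir, paste0(cid, "_cut.stl")), sidecar = FALSE)
    write_skull_stl(list(vertices = res$final_vertices, faces = sol$model$tris),
                    file.path(dir, paste0(cid, "_final.stl")), sidecar = FALSE)
    write_vtk(list(vertices = sol$model$nodes, faces = sol$model$tris),
              file.path(dir, paste0(cid, "_final.vtk")),
              point_data = list(displacement = res$displacements[[length(res$displacements)]]))
    jsonlite::write_json(out, file.path(dir, paste0(cid, "_report.json")),
                         auto_unbox = TRUE, digits = 10)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full parametric study on a synthetic cohort
#'
#' For every case: builds the patient-specific parameter space, draws the
#' space-filling design (25 points for two-spring cases, 27 for four-spring
#' cases), solves the expansion at every design point, fits the quadratic
#' response surface and extracts the local sensitivity chart at the
#' as-operated reference.  Sensitivities are then averaged per procedure
#' group and compared between groups.  Per-case design points that fail
#' (infeasible cuts or non-converged solves) are recorded and excluded from
#' the fit; the study continues.
#'
#' @param config a [study_config()] (or overrides accepted by it).
#' @param solve run the FE solves (default); `solve = FALSE` builds cohort,
#'   spaces and designs only (design bookkeeping, no simulation).
#' @param verbose print per-case progress.
#' @return object of class `study_report`: per-case entries, the pooled
#'   `group_summary`, design-point bookkeeping and the configuration hash.
#' @export
run_study <- function(config = study_config(), solve = TRUE, verbose = FALSE) {
  if (!inherits(config, "study_config")) config <- study_config(config)
  cohort <- cohort_from_config(config)
  entries <- list()
  charts <- list()
  n_points_total <- 0L
  for (ci in seq_along(cohort)) {
    cs <- cohort[[ci]]
    entry <- list(case_id = cs$case_id, procedure = cs$procedure)
    surface <- align_to_frame(cs$surface)$surface
    if (config$cohort$growth_factor != 1) {
      surface <- scale_for_growth(surface, config$cohort$growth_factor)
    }
    params <- case_baseline(surface, config)
    placements <- procedure_placements(cs$procedure,
                                       s_t = config$springs$s_t,
                                       s_l = config$springs$s_l,
                                       spring_model = config$springs$model)
    space <- build_parameter_space(surface,
                                   list(params = params, placements = placements),
                                   cs$procedure)
    n_req <- config$doe[[switch(cs$procedure, T2 = "n_t2", L2 = "n_l2",
                                TL4 = "n_tl4")]]
    design <- optimal_space_filling(space, n_samples = n_req,
                                    seed = derive_seed(config$doe$seed, ci),
                                    max_sweeps = config$doe$max_sweeps)
    entry$n_design_points <- nrow(design$samples)
    n_points_total <- n_points_total + nrow(design$samples)
    entry$design <- design
    if (solve) {
      responses <- rep(NA_real_, nrow(design$samples))
      failures <- character(nrow(design$samples))
      for (ri in seq_len(nrow(design$samples))) {
        row <- design$samples[ri, ]
        p_i <- osteotomy_params(L = row[["L"]], H = row[["H"]],
                                alpha = row[["alpha"]], kerf = params$kerf)
        pl_i <- procedure_placements(
          cs$procedure,
          s_t = if ("S_T" %in% names(row)) row[["S_T"]] else config$springs$s_t,
          s_l = if ("S_L" %in% names(row)) row[["S_L"]] else config$springs$s_l,
          spring_model = config$springs$model)
        res <- tryCatch({
          sol <- solve_one(surface, p_i, pl_i, config)
          if (!sol$result$newton_converged) stop("solver did not converge")
          sol$result$icv_ml[length(sol$result$icv_ml)]
        }, error = function(e) {
          failures[ri] <<- conditionMessage(e)
          NA_real_
        })
        responses[ri] <- res
      }
      entry$responses <- responses
      entry$failures <- failures[failures != ""]
      fit <- tryCatch(fit_response_surface(design, responses),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        entry$error <- conditionMessage(fit)
      } else {
        entry$response_surface <- fit
        chart <- tryCatch(
          local_sensitivity(fit, space, case_id = cs$case_id,
                            procedure = cs$procedure),
          error = function(e) e)
        if (inherits(chart, "error")) {
          entry$error <- conditionMessage(chart)
        } else {
          entry$chart <- chart
          charts[[length(charts) + 1L]] <- chart
          entry$extremes <- extreme_configurations(design, responses)
        }
      }
      if (verbose) {
        message(sprintf("%s: %d/%d design points solved", cs$case_id,
                        sum(is.finite(responses)), length(responses)))
      }
    }
    entries[[ci]] <- entry
  }
  groups <- if (length(charts) >= 2) group_average(charts) else NULL
  structure(list(cases = entries, charts = charts, groups = groups,
                 n_design_points_total = n_points_total,
                 config_hash = config_hash(unclass(config)),
                 solved = solve),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d sensitivity charts, %d design points total\n",
              length(x$charts), x$n_design_points_total))
  if (!is.null(x$groups)) print(x$groups)
  invisible(x)
}

#' Export a study report to CSV/JSON
#'
#' Writes the per-group summary table, the per-case sensitivity charts and
#' the between-group comparisons.
#'
#' @param report a [run_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_study <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$groups)) {
    write.csv(report$groups$summary, file.path(dir, "group_summary.csv"),
              row.names = FALSE)
    if (!is.null(report$groups$comparisons)) {
      write.csv(report$groups$comparisons, file.path(dir, "group_comparisons.csv"),
                row.names = FALSE)
    }
  }
  charts <- lapply(report$charts, function(ch) {
    list(case_id = ch$case_id, procedure = ch$procedure,
         reference = as.list(ch$reference),
         sensitivities = ch$sensitivities)
  })
  jsonlite::write_json(list(n_design_points_total = report$n_design_points_total,
                            config_hash = report$config_hash, charts = charts),
                       file.path(dir, "study_report.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(dir)
}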