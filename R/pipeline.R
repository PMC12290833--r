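#' Validate a pipeline configuration
#'
#' A config is a list (or a JSON/YAML file path) with fields: \code{input}
#' (paths: image, bval, bvec) or \code{phantom} (a preset name), \code{base}
#' (output filename stem), \code{out_dir}, \code{seed}, and \code{steps} — an
#' ordered list of steps, each \code{list(step = <name>, ...options)}.
#' Implemented steps: noise-estimate, rbc, dti, dki, dkiax, wmti-watson,
#' noddi-dti, relmask. The config is rejected when both an "rbc" step and a
#' Rician-aware NLLS fit are requested (the Rician-aware prediction assumes
#' uncorrected data).
#'
#' @param config list or path.
#' @return the normalized config list (invisibly errors otherwise).
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  known <- c("noise-estimate", "rbc", "dti", "dki", "dkiax",
             "wmti-watson", "noddi-dti", "relmask")
  steps <- vapply(config$steps, function(s) s$step, character(1))
  bad <- setdiff(steps, known)
  if (length(bad)) stop("unknown pipeline steps: ", paste(bad, collapse = ", "))
  rician <- vapply(config$steps, function(s)
    isTRUE(s$ricianAware) || identical(s$ricianAware, "true"), logical(1))
  if ("rbc" %in% steps && any(rician))
    stop("config requests both RBC and Rician-aware NLLS; ",
         "these are mutually exclusive")
  if (is.null(config$seed)) config$seed <- 1L
  config
}

readPipelineConfig <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Run a linear processing pipeline
#'
#' Executes the configured steps in order; each step receives the output of
#' the previous ones. Every intermediate volume is written via the BIDS
#' derivative naming (concatenated desc labels), and a JSON provenance record
#' (package version, options, seed, input hashes) is written next to the
#' outputs. The first failing step aborts with a step-named error; outputs
#' written before the failure are retained.
#'
#' @param config see \code{\link{validatePipelineConfig}}.
#' @return invisibly, a list with \code{status} (0 on success), the
#'   provenance record, and the in-memory results.
#' @export
runPipeline <- function(config) {
  config <- validatePipelineConfig(config)
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  base <- if (is.null(config$base)) "phantom_dwi" else config$base
  seed <- as.integer(config$seed)
  input_hashes <- NULL
  if (!is.null(config$input)) {
    dwi <- readDWI(config$input$image, config$input$bval, config$input$bvec)
    input_hashes <- vapply(unlist(config$input), function(p)
      unname(tools::md5sum(p)), character(1))
  } else if (!is.null(config$phantom)) {
    ph <- phantomFromConfig(config$phantom, seed)
    dwi <- ph$dwi
  } else stop("config needs either input paths or a phantom spec")
  state <- list(dwi = dwi, noise = NULL, results = list())
  for (s in config$steps) {
    state <- tryCatch(
      runPipelineStep(state, s, base = base, out_dir = out_dir, seed = seed),
      error = function(e)
        stop(sprintf("pipeline step '%s' failed: %s", s$step,
                     conditionMessage(e)), call. = FALSE))
  }
  prov <- list(
    package = "dwikit",
    version = as.character(packageVersion("dwikit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config[setdiff(names(config), "steps")],
    steps = config$steps,
    input_md5 = as.list(input_hashes))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov_path <- file.path(out_dir, paste0(base, "_provenance.json"))
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(list(status = 0L, provenance = prov, results = state$results,
                 provenance_path = prov_path))
}

phantomFromConfig <- function(phcfg, seed) {
  preset <- if (is.character(phcfg)) phcfg else phcfg$preset
  sch <- schemePreset(preset, seed = seed)
  gt <- list(D = diag(c(1.7e-3, 0.4e-3, 0.4e-3)),
             W = axiTensors(c(1, 0, 0), 1.7e-3, 0.4e-3, 0.8, 0.5, 1.5)$w)
  grid <- c(8L, 8L, 4L)
  ph <- synthesizePhantom(list(grid = grid, scheme = sch,
                               layout = "uniform", regions = list(gt)))
  sigma_cfg <- if (is.list(phcfg) && !is.null(phcfg$sigma)) phcfg$sigma else 0
  if (sigma_cfg > 0)
    ph$dwi <- addNoise(ph$dwi, sigma_cfg,
                       if (is.list(phcfg) && !is.null(phcfg$ncoils))
                         phcfg$ncoils else 1L, seed = seed)
  ph
}

runPipelineStep <- function(state, s, base, out_dir, seed) {
  opt <- s
  dwi <- state$dwi
  if (s$step == "noise-estimate") {
    mask <- if (!is.null(opt$background_fraction)) {
      # crude background: darkest fraction of the mean b0 volume
      b0 <- apply(dwi@data[, , , shellIds(scheme(dwi)) == 0L, drop = FALSE],
                  1:3, mean)
      q <- quantile(b0, opt$background_fraction)
      array((b0 <= q) * 1L, dim(b0))
    } else array(1L, dim(dwi@data)[1:3])
    ncoils <- if (is.null(opt$ncoils)) 1L else as.integer(opt$ncoils)
    if (!is.null(opt$sigma)) {
      state$noise <- new("NoiseEstimate", sigma = as.numeric(opt$sigma),
                         ncoils = ncoils, method = "standard",
                         nSamples = 0L)
    } else {
      state$noise <- estimateNoiseStandard(dwi, mask, ncoils)
    }
    state$results$noise <- state$noise
  } else if (s$step == "rbc") {
    if (is.null(state$noise)) stop("rbc needs a prior noise-estimate step")
    dwi <- ricianBiasCorrect(dwi, state$noise)
    writeDerivative(dwi, base, out_dir = out_dir, overwrite = TRUE)
    state$dwi <- dwi
  } else if (s$step %in% c("dti", "dki", "dkiax")) {
    algo <- toupper(if (is.null(opt$algo)) "OLS" else opt$algo)
    if (algo == "ROBUST") algo <- "ROB"
    rice <- isTRUE(opt$ricianAware)
    fit <- switch(s$step,
      dti = fitDTI(dwi, algorithm = algo, noise = state$noise,
                   ricianAware = rice),
      dki = fitDKI(dwi, algorithm = if (algo == "OLS") "OLS" else "NLLS",
                   noise = state$noise, ricianAware = rice),
      dkiax = fitAxisymmetricDKI(dwi, noise = state$noise,
                                 ricianAware = rice))
    model_lab <- switch(s$step, dti = "DTI", dki = "DKI", dkiax = "DKIax")
    algo_lab <- if (s$step == "dkiax") "NLLS" else algo
    state$results[[s$step]] <- fit
    mets <- if (s$step == "dti") dtiMetrics(fit) else
      if (s$step == "dki") c(dtiMetrics(fit), dkiMetrics(fit)) else NULL
    if (!is.null(mets)) {
      for (nm in intersect(names(mets), bidsLabels))
        writeDerivative(mets[[nm]],
                        paste0(base),
                        labels = c(descLabels(dwi), model_lab, algo_lab, nm),
                        out_dir = out_dir, step = model_lab,
                        voxelSize = dwi@voxelSize, overwrite = TRUE)
      state$results[[paste0(s$step, "_metrics")]] <- mets
    }
    writeDerivative(rmsErrorMap(fit), base,
                    labels = c(descLabels(dwi), model_lab, algo_lab,
                               "RMS-ERROR"),
                    out_dir = out_dir, step = model_lab,
                    voxelSize = dwi@voxelSize, overwrite = TRUE)
  } else if (s$step == "wmti-watson") {
    fit <- state$results$dkiax
    if (is.null(fit)) stop("wmti-watson needs a prior dkiax step")
    branch <- if (is.null(opt$branch)) "plus" else opt$branch
    maps <- wmtiWatsonFit(fit, branch = branch)
    for (nm in c("AWF", "DA", "DE_PARA", "DE_PERP", "KAPPA", "ODI"))
      writeDerivative(maps[[nm]], base,
                      labels = c("WMTI-W", sub("_", "-", nm)),
                      out_dir = out_dir, step = "WMTI-W",
                      voxelSize = state$dwi@voxelSize, overwrite = TRUE)
    state$results$wmti <- maps
  } else if (s$step == "noddi-dti") {
    fit <- state$results$dti
    if (is.null(fit)) stop("noddi-dti needs a prior dti step")
    mets <- state$results$dti_metrics
    d_fixed <- if (!is.null(opt$d)) as.numeric(opt$d) else
      noddiDTIPresets()[[if (is.null(opt$preset)) "invivo" else opt$preset]]
    maps <- noddiDTI(mets$FA, mets$MD, d_fixed)
    for (nm in c("f", "kappa", "odi")) {
      lab <- c(f = "AWF", kappa = "KAPPA", odi = "ODI")[[nm]]
      writeDerivative(maps[[nm]], base, labels = c("NODDI-DTI", lab),
                      out_dir = out_dir, step = "NODDI-DTI",
                      voxelSize = state$dwi@voxelSize, overwrite = TRUE)
    }
    state$results$noddi <- maps
  } else if (s$step == "relmask") {
    fit <- state$results$dti
    if (is.null(fit)) fit <- state$results$dki
    if (is.null(fit)) stop("relmask needs a prior fit step")
    thr <- if (is.null(opt$threshold)) stop("relmask needs a threshold") else
      as.numeric(opt$threshold)
    rm_ <- reliabilityMask(rmsErrorMap(fit), thr)
    writeDerivative(rm_, base, labels = character(), out_dir = out_dir,
                    step = "RELMASK", voxelSize = state$dwi@voxelSize,
                    overwrite = TRUE)
    state$results$relmask <- rm_
  }
  state
}

#' Re-run a pipeline from its provenance record
#'
#' The provenance JSON written by \code{\link{runPipeline}} contains the full
#' config and seed, so replaying reconstructs identical outputs.
#'
#' @param provenance_path path to a \code{*_provenance.json} file.
#' @param out_dir optional override for the output root.
#' @export
replayPipeline <- function(provenance_path, out_dir = NULL) {
  prov <- jsonlite::read_json(provenance_path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  config <- c(prov$config, list(steps = prov$steps))
  config$seed <- prov$seed
  if (!is.null(out_dir)) config$out_dir <- out_dir
  runPipeline(config)
}
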