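#' @include AllClasses.R
NULL

.readLayout <- function(layout) {
  if (is.character(layout)) layout <- utils::read.csv(layout,
                                                      comment.char = "#",
                                                      stringsAsFactors = FALSE)
  required <- c("well", "compound", "concentration_um")
  missing <- setdiff(required, names(layout))
  if (length(missing))
    stop("layout schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  layout$group <- ifelse(layout$concentration_um == 0, "control",
                         sprintf("%s_%g", layout$compound,
                                 layout$concentration_um))
  layout
}

.writeManifest <- function(outDir, config, extra = list()) {
  manifest <- c(list(configHash = configHash(config),
                     config = sapply(slotNames(config), function(nm)
                       slot(config, nm), simplify = FALSE)),
                extra)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the cardiotoxicity assay over a plate
#'
#' Analyses one video per well (file `<well>.tif` under `videoDir`), writes
#' a per-embryo CSV, a per-group summary (median rate, category counts,
#' Mann-Whitney against the vehicle control) and a JSON run manifest
#' carrying the config hash. Groups with fewer than 10 analysable embryos
#' are flagged and excluded from the group test; a minimum of 10 embryos
#' per treated group is required for statistics.
#'
#' @param videoDir directory of well videos
#' @param layout data.frame or CSV path with columns `well`, `compound`,
#'   `concentration_um` (0 = vehicle control)
#' @param config an [AssayConfig-class]
#' @param outDir output directory (created if needed)
#' @return invisibly, a list with `embryos` and `groups` data frames
#' @export
runCardioPlate <- function(videoDir, layout, config = assayConfig(),
                           outDir = videoDir) {
  layout <- .readLayout(layout)
  if (!any(layout$concentration_um == 0)) stop("missing control group")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    path <- file.path(videoDir, paste0(layout$well[i], ".tif"))
    base <- data.frame(well = layout$well[i], compound = layout$compound[i],
                       concentration_um = layout$concentration_um[i],
                       group = layout$group[i])
    res <- tryCatch({
      stack <- readFrameStack(path)
      analyzeCardioVideo(stack, config)
    }, error = function(e) {
      message("well ", layout$well[i], " flagged: ", conditionMessage(e))
      NULL
    })
    if (is.null(res))
      return(cbind(base, category = NA, heart_rate_hz = NA,
                   beats_per_15s = NA, n_sig_freqs = NA, of_amplitude = NA,
                   analysable = FALSE))
    cbind(base, category = category(res), heart_rate_hz = heartRateHz(res),
          beats_per_15s = beatsPer15s(res),
          n_sig_freqs = nSignificantFreqs(res),
          of_amplitude = ofAmplitude(res), analysable = isAnalysable(res))
  })
  embryos <- do.call(rbind, rows)
  usable <- embryos$analysable & !is.na(embryos$category) &
    embryos$category != "NO_CALL"
  ctl <- embryos[usable & embryos$group == "control", ]
  groups <- lapply(split(embryos, embryos$group), function(g) {
    ok <- g[g$analysable & !is.na(g$category) & g$category != "NO_CALL", ]
    counts <- table(factor(ok$category, levels = CARDIO_CATEGORIES))
    flagged <- nrow(ok) < 10
    p <- NA_real_
    if (!flagged && g$group[1] != "control" && nrow(ctl) >= 10)
      p <- pValue(mannWhitney(ok$beats_per_15s, ctl$beats_per_15s))
    data.frame(group = g$group[1], compound = g$compound[1],
               concentration_um = g$concentration_um[1],
               n = nrow(g), n_analysable = nrow(ok),
               median_beats_per_15s = stats::median(ok$beats_per_15s),
               predominant = if (nrow(ok)) names(which.max(counts))
                             else NA_character_,
               n_no_effect = unname(counts["NO_EFFECT"]),
               n_bradycardia = unname(counts["BRADYCARDIA"]),
               n_arrhythmia_21 = unname(counts["ARRHYTHMIA_21"]),
               n_cardiac_arrest = unname(counts["CARDIAC_ARREST"]),
               flagged = flagged, p_vs_control = p)
  })
  groups <- do.call(rbind, groups)
  rownames(groups) <- NULL
  utils::write.csv(embryos, file.path(outDir, "cardio_embryos.csv"),
                   row.names = FALSE)
  utils::write.csv(groups, file.path(outDir, "cardio_groups.csv"),
                   row.names = FALSE)
  .writeManifest(outDir, config,
                 list(assay = "cardio", seed = config@seed,
                      nWells = nrow(layout)))
  invisible(list(embryos = embryos, groups = groups))
}

#' Run the angiogenesis assay over a plate
#'
#' Quantifies one trunk image per well (`<well>.tif` under `imageDir`),
#' writes the per-embryo vessel quantification CSV, a per-group summary with
#' ANOVA + Dunnett-adjusted comparisons of enclosed area against the vehicle
#' control and the inhibition call, an IC50 fit (4PL on the complete-ISV
#' count) for every compound with at least 5 concentrations, and a JSON
#' manifest. Unreadable or empty wells are flagged and the run completes.
#'
#' @param imageDir directory of well images
#' @param layout data.frame or CSV path (`well`, `compound`,
#'   `concentration_um`; 0 = vehicle control)
#' @param config an [AssayConfig-class]
#' @param outDir output directory
#' @return invisibly, a list with `embryos`, `groups` and `ic50` data frames
#' @export
runAngioPlate <- function(imageDir, layout, config = assayConfig(),
                          outDir = imageDir) {
  layout <- .readLayout(layout)
  if (!any(layout$concentration_um == 0)) stop("missing control group")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    path <- file.path(imageDir, paste0(layout$well[i], ".tif"))
    base <- data.frame(well = layout$well[i], compound = layout$compound[i],
                       concentration_um = layout$concentration_um[i],
                       group = layout$group[i])
    q <- tryCatch(quantifyVessels(readGrayImage(path), config),
                  error = function(e) {
                    message("well ", layout$well[i], " flagged: ",
                            conditionMessage(e))
                    NULL
                  })
    if (is.null(q))
      return(cbind(base, enclosed_area_px = NA, n_enclosed_regions = NA,
                   total_isvs = NA, complete_isvs = NA, rails_found = NA,
                   length_px = NA, flagged = TRUE))
    cbind(base, enclosed_area_px = enclosedAreaPx(q),
          n_enclosed_regions = nEnclosedRegions(q),
          total_isvs = totalISVs(q), complete_isvs = completeISVs(q),
          rails_found = railsFound(q), length_px = embryoLengthPx(q),
          flagged = FALSE)
  })
  embryos <- do.call(rbind, rows)
  ok <- embryos[!embryos$flagged, ]
  groupNames <- unique(ok$group)
  sizes <- table(ok$group)
  eligible <- names(sizes)[sizes >= 10]
  adj <- NULL
  if ("control" %in% eligible && length(eligible) >= 2) {
    gl <- split(ok$enclosed_area_px, ok$group)[eligible]
    ci <- match("control", names(gl))
    adj <- anovaDunnett(gl, controlIndex = ci, alpha = config@alpha)
  }
  groups <- lapply(split(embryos, embryos$group), function(g) {
    gg <- g[!g$flagged, ]
    nm <- g$group[1]
    flagged <- nrow(gg) < 10
    padj <- NA_real_
    call <- NA_character_
    if (!is.null(adj) && nm %in% names(adj$comparisons)) {
      cmp <- adj$comparisons[[nm]]
      padj <- adjustedP(cmp)
      ctlMean <- mean(ok$enclosed_area_px[ok$group == "control"])
      call <- if (padj < config@alpha &&
                  mean(gg$enclosed_area_px) < ctlMean) "INHIBITED"
              else "NOT_INHIBITED"
    }
    data.frame(group = nm, compound = g$compound[1],
               concentration_um = g$concentration_um[1], n = nrow(g),
               n_ok = nrow(gg),
               mean_enclosed_area = mean(gg$enclosed_area_px),
               mean_total_isvs = mean(gg$total_isvs),
               mean_complete_isvs = mean(gg$complete_isvs),
               adjusted_p = padj, call = call, flagged = flagged)
  })
  groups <- do.call(rbind, groups)
  rownames(groups) <- NULL
  ## IC50 across each compound's concentration series
  ic50 <- lapply(setdiff(unique(ok$compound[ok$concentration_um > 0]), NA),
                 function(cmp) {
    sub <- ok[ok$compound == cmp & ok$concentration_um > 0 &
              !is.na(ok$complete_isvs), ]
    if (length(unique(sub$concentration_um)) < 5) return(NULL)
    fit <- fit4PL(sub$concentration_um, sub$complete_isvs)
    data.frame(compound = cmp, ic50_um = fit$ic50, hill = fit$hill,
               top = fit$top, bottom = fit$bottom,
               converged = fit$converged)
  })
  ic50 <- do.call(rbind, ic50)
  utils::write.csv(embryos, file.path(outDir, "angio_embryos.csv"),
                   row.names = FALSE)
  utils::write.csv(groups, file.path(outDir, "angio_groups.csv"),
                   row.names = FALSE)
  if (!is.null(ic50))
    utils::write.csv(ic50, file.path(outDir, "angio_ic50.csv"),
                     row.names = FALSE)
  .writeManifest(outDir, config,
                 list(assay = "angio", seed = config@seed,
                      nWells = nrow(layout)))
  invisible(list(embryos = embryos, groups = groups, ic50 = ic50))
}
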