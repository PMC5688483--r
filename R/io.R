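# Read/write a config document by extension (.yaml/.yml or .json).
read_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  doc <- tryCatch(
    switch(ext,
      yaml = , yml = yaml::read_yaml(path),
      json = jsonlite::read_json(path, simplifyVector = FALSE),
      stop(sprintf("unsupported config extension '.%s' (use .yaml or .json)",
                   ext), call. = FALSE)
    ),
    error = function(e) {
      stop(sprintf("cannot parse %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  doc
}

write_config <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(x, path, precision = 15),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE),
    stop(sprintf("unsupported config extension '.%s' (use .yaml or .json)",
                 ext), call. = FALSE)
  )
  invisible(path)
}

#' Read and write country profiles and scenarios
#'
#' Profiles and scenarios are plain YAML or JSON documents mirroring the
#' fields of \code{\link{country_profile}} and \code{\link{scenario}}. All
#' fractions are decimals in \code{[0, 1]}, never percents: values above 1 are
#' rejected rather than rescaled. A profile must carry either a
#' \code{stillbirths} count or an \code{sbr}; both absent is a schema error.
#' Invariant violations are reported with the offending field's path.
#'
#' @param path File path (\code{.yaml}/\code{.yml} or \code{.json}).
#' @param profile A \code{\link{country_profile}}.
#' @param scn A \code{\link{scenario}}.
#' @return \code{read_profile} / \code{read_scenario} return validated
#'   objects; the writers return \code{path} invisibly.
#' @export
read_profile <- function(path) {
  doc <- read_config(path)
  required <- c("births_per_year", "prop_intrapartum")
  missing <- setdiff(required, names(doc))
  if (is.null(doc$stillbirths) && is.null(doc$sbr)) {
    missing <- c(missing, "stillbirths|sbr")
  }
  if (length(missing)) {
    stop(sprintf("profile %s is missing required fields: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  country_profile(
    births_per_year = doc$births_per_year,
    stillbirths = doc$stillbirths, sbr = doc$sbr,
    prop_intrapartum = doc$prop_intrapartum,
    prevalences = doc$prevalences %||% list(),
    baseline_indicators = doc$baseline_indicators %||% list(),
    name = doc$name %||% NA_character_
  )
}

#' @rdname read_profile
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "country_profile"))
  doc <- list(
    name = if (is.na(profile$name)) NULL else profile$name,
    births_per_year = profile$births_per_year,
    stillbirths = profile$stillbirths,
    prop_intrapartum = profile$prop_intrapartum,
    prevalences = profile$prevalences,
    baseline_indicators = profile$baseline_indicators
  )
  write_config(Filter(Negate(is.null), doc), path)
}

#' @rdname read_profile
#' @export
read_scenario <- function(path) {
  doc <- read_config(path)
  missing <- setdiff(c("base_year", "end_year"), names(doc))
  if (length(missing)) {
    stop(sprintf("scenario %s is missing required fields: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  scenario(base_year = doc$base_year, end_year = doc$end_year,
           targets = doc$targets %||% list(),
           trajectory = doc$trajectory %||% "linear")
}

#' @rdname read_profile
#' @export
write_scenario <- function(scn, path) {
  stopifnot(inherits(scn, "scenario"))
  write_config(list(base_year = scn$base_year, end_year = scn$end_year,
                    targets = scn$targets, trajectory = scn$trajectory),
               path)
}

#' Write an impact report
#'
#' Emits a CSV table with one row per year x intervention x timing
#' (columns \code{year}, \code{intervention}, \code{timing}, \code{averted})
#' followed by per-year summary rows (\code{intervention = "_total_"},
#' \code{timing = "all"}, with \code{residual} and \code{sbr} filled), plus a
#' human-readable text summary including the ENAP target status. The CSV is
#' UTF-8, comma-delimited, with a \code{.} decimal separator and a fixed
#' column order; averted counts are carried at full precision in the CSV and
#' rounded to whole stillbirths only in the text summary.
#'
#' @param result An \code{\link{run_scenario}} result.
#' @param path Output CSV path; the text summary goes to the same path with
#'   extension \code{.txt}.
#' @return Invisibly, paths of the files written.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "impact_result"))
  bi <- result$by_intervention
  bi$residual <- NA_real_
  bi$sbr <- NA_real_
  totals <- data.frame(
    year = result$by_year$year, intervention = "_total_", timing = "all",
    averted = result$by_year$averted_antepartum +
      result$by_year$averted_intrapartum,
    residual = result$by_year$residual, sbr = result$by_year$sbr
  )
  tab <- rbind(bi[c("year", "intervention", "timing", "averted", "residual",
                    "sbr")], totals)
  tab <- tab[order(tab$year, tab$intervention != "_total_", tab$intervention,
                   tab$timing), ]
  utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")

  last <- result$by_year[nrow(result$by_year), ]
  txt_path <- paste0(tools::file_path_sans_ext(path), ".txt")
  lines <- c(
    sprintf("Stillbirth scale-up projection %d-%d (%s trajectory)",
            result$meta$base_year, result$meta$end_year,
            result$meta$trajectory),
    sprintf("Total births per year: %s",
            format(result$meta$births_per_year, big.mark = ",")),
    sprintf("End-year stillbirths averted: %s (antepartum %s, intrapartum %s)",
            format(round(last$averted_antepartum + last$averted_intrapartum),
                   big.mark = ","),
            format(round(last$averted_antepartum), big.mark = ","),
            format(round(last$averted_intrapartum), big.mark = ",")),
    sprintf("End-year residual stillbirths: %s",
            format(round(last$residual), big.mark = ",")),
    sprintf("End-year stillbirth rate: %.2f per 1000 total births", last$sbr),
    sprintf("ENAP target (<=12 per 1000): %s",
            ifelse(last$enap_met, "met", "not met"))
  )
  writeLines(lines, txt_path)
  invisible(c(csv = path, txt = txt_path))
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Run manifest
#'
#' Records everything needed to reproduce a run bit-for-bit given the same
#' package version: version, a hash of the serialized registry, input paths,
#' seeds and a timestamp.
#'
#' @param registry Intervention registry used.
#' @param profile_path,scenario_path Input document paths (or \code{NA}).
#' @param seed Seed(s) used for any stochastic component.
#' @return A list of class \code{"run_manifest"}.
#' @export
run_manifest <- function(registry, profile_path = NA_character_,
                         scenario_path = NA_character_, seed = NA_integer_) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_registry(registry, tmp)
  structure(
    list(
      tool_version = as.character(utils::packageVersion("stillavert")),
      registry_hash = unname(tools::md5sum(tmp)),
      profile_path = profile_path, scenario_path = scenario_path,
      seed = seed, timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ")
    ),
    class = "run_manifest"
  )
}

#' @rdname run_manifest
#' @param manifest A \code{"run_manifest"}.
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
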