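#' Construct a ReferenceRange
#'
#' @param name biomarker name
#' @param green numeric(2) inclusive normal interval
#' @param yellow numeric(2) inclusive borderline interval containing the
#'   green one (defaults to the green interval: no yellow band)
#' @param direction \code{"high_bad"}, \code{"low_bad"} or
#'   \code{"two_sided"}
#' @param source free-text provenance note
#' @return a [ReferenceRange-class]
#' @export
referenceRange <- function(name, green, yellow = green,
                           direction = "two_sided", source = "") {
  new("ReferenceRange", name = name, green = as.numeric(green),
      yellow = as.numeric(yellow), direction = direction, source = source)
}

#' Mean +/- SD reference range
#'
#' Two-sided range with green = within one SD of the mean and yellow =
#' within two SDs; beyond two SDs is red.
#'
#' @param name biomarker name
#' @param mean,sd population mean and standard deviation
#' @param source free-text provenance note
#' @return a [ReferenceRange-class]
#' @export
meanSdRange <- function(name, mean, sd, source = "") {
  referenceRange(name, green = c(mean - sd, mean + sd),
                 yellow = c(mean - 2 * sd, mean + 2 * sd),
                 direction = "two_sided", source = source)
}

#' Three-way traffic-light banding of a value
#'
#' Deterministic green/yellow/red status from a [ReferenceRange-class]:
#' inside the green interval (inclusive) is green, inside the yellow
#' interval is yellow, everything else red. Boundary values belong to the
#' greener band; a missing value yields \code{not_evaluated}.
#'
#' @param value numeric scalar (NA allowed)
#' @param range a [ReferenceRange-class]
#' @return one of \code{"green"}, \code{"yellow"}, \code{"red"},
#'   \code{"not_evaluated"}
#' @examples
#' r <- meanSdRange("VFA", 150, 75)
#' band(338, r)  # "red"
#' @export
band <- function(value, range) {
  stopifnot(is(range, "ReferenceRange"))
  if (is.na(value)) return("not_evaluated")
  if (value >= range@green[1] && value <= range@green[2]) return("green")
  if (value >= range@yellow[1] && value <= range@yellow[2])
    return("yellow")
  "red"
}

# Map an ordered category to a traffic-light status.
.statusFromCategory <- function(category, greenSet, yellowSet) {
  if (is.na(category)) return("not_evaluated")
  if (category %in% greenSet) return("green")
  if (category %in% yellowSet) return("yellow")
  "red"
}

#' Section conclusion text
#'
#' Synthesizes the per-comorbidity conclusion from template strings keyed
#' on the section's category labels: the CAC band drives the statin
#' sentence, the Lung-RADS category the follow-up interval, the T-score
#' class the osteoporosis sentence, and so on. Templates live in config,
#' not code, so guideline wording can be updated without a release.
#'
#' @param sectionName one of \code{"adipose"}, \code{"cardio"},
#'   \code{"lung"}, \code{"nodules"}, \code{"bone"}
#' @param results list of [BiomarkerResult-class] for the section
#' @param extra list of section-specific category facts (e.g.
#'   \code{lungrads}, \code{cac_label}, \code{steatosis_grade})
#' @param config configuration list
#' @return character conclusion (possibly multi-sentence)
#' @export
concludeSection <- function(sectionName, results, extra = list(),
                            config = defaultConfig()) {
  tpl <- config$templates
  st <- vapply(results, status, character(1))
  parts <- character(0)
  if (sectionName == "adipose") {
    fat <- st[vapply(results, function(r) r@name %in% c("VFA", "SFA"),
                     logical(1))]
    if (any(fat == "red" | fat == "yellow")) {
      parts <- c(parts, tpl$fat_abnormal)
    } else if (any(fat != "not_evaluated")) {
      parts <- c(parts, tpl$fat_normal)
    }
    g <- extra$steatosis_grade
    if (!is.null(g) && !is.na(g)) {
      parts <- c(parts, if (g == "none") tpl$steatosis_none else
        sprintf(tpl$steatosis,
                paste0(toupper(substring(g, 1, 1)), substring(g, 2))))
    }
  } else if (sectionName == "cardio") {
    if (!is.null(extra$cac_label) && nzchar(extra$cac_label))
      parts <- c(parts, sprintf("%s.", extra$cac_label))
    highs <- extra$high_vessels
    if (length(highs))
      parts <- c(parts, sprintf(tpl$vessel_high,
                                paste(highs, collapse = " and ")))
    if (!is.null(extra$statin) && nzchar(extra$statin))
      parts <- c(parts, extra$statin)
  } else if (sectionName == "nodules") {
    lr <- extra$lungrads
    if (is.null(lr) || identical(lr$category, "1")) {
      parts <- c(parts, tpl$nodule_none)
    } else {
      parts <- c(parts, sprintf(tpl$nodule_found, lr$category),
                 lr$recommendation)
    }
  } else if (sectionName == "lung") {
    ei <- extra$emphysema_index
    if (!is.null(ei) && !is.na(ei)) {
      lc <- config$lung
      parts <- c(parts, if (ei <= lc$ei_green_max) tpl$emphysema_none
        else if (ei <= lc$ei_yellow_max) tpl$emphysema_mild
        else tpl$emphysema_severe)
    }
    if (isTRUE(extra$wall_thickening))
      parts <- c(parts, tpl$wall_thickening)
  } else if (sectionName == "bone") {
    cls <- extra$bone_class
    if (!is.null(cls) && !is.na(cls)) {
      parts <- c(parts, switch(cls,
        osteoporosis = tpl$bone_osteoporosis,
        osteopenia = tpl$bone_osteopenia,
        normal = tpl$bone_normal))
    }
  }
  if (!length(parts)) {
    parts <- if (length(st) && all(st %in% c("green", "not_evaluated")))
      tpl$all_normal else ""
  }
  paste(parts[nzchar(parts)], collapse = " ")
}

#' Assemble a structured report document
#'
#' @param sections named list; each element a list with \code{title},
#'   \code{results} (list of [BiomarkerResult-class]) and
#'   \code{conclusion}
#' @param meta list of opaque study identifiers
#' @param thumbnails character vector of image file references
#' @param provenance list of version/parameter provenance (the package
#'   version is added automatically)
#' @return a [ReportDocument-class]
#' @export
assembleReport <- function(sections, meta = list(), thumbnails = character(0),
                           provenance = list()) {
  provenance$package <- "ctscreen"
  provenance$version <- as.character(utils::packageVersion("ctscreen"))
  new("ReportDocument", meta = meta, sections = sections,
      thumbnails = thumbnails, provenance = provenance)
}

# Plain-list form of a report document (the JSON twin).
.reportAsList <- function(doc) {
  list(
    meta = doc@meta,
    sections = lapply(doc@sections, function(s) list(
      title = s$title,
      results = lapply(s$results, function(r) list(
        name = r@name,
        value = if (is.na(r@value)) NULL else r@value,
        units = r@units,
        status = r@status,
        category_label = r@categoryLabel,
        recommendation = r@recommendation,
        provenance = r@provenance)),
      conclusion = s$conclusion)),
    thumbnails = as.list(doc@thumbnails),
    provenance = doc@provenance)
}

#' Validate the structure of a report document
#'
#' Structural check mirroring the shipped JSON schema
#' (\code{inst/extdata/report-schema.json}): every section carries title,
#' results and conclusion; every result carries name, units, status in
#' the allowed set, and a value exactly when its status is not
#' \code{not_evaluated}.
#'
#' @param doc a [ReportDocument-class] or the plain list form
#' @return TRUE invisibly; stops with a message on violation
#' @export
validateReport <- function(doc) {
  x <- if (is(doc, "ReportDocument")) .reportAsList(doc) else doc
  if (!all(c("meta", "sections", "provenance") %in% names(x)))
    stop("report must have meta, sections and provenance")
  if (!length(x$sections)) stop("report must contain at least one section")
  for (nm in names(x$sections)) {
    s <- x$sections[[nm]]
    if (!all(c("title", "results", "conclusion") %in% names(s)))
      stop(sprintf("section '%s' incomplete", nm))
    for (r in s$results) {
      if (!all(c("name", "units", "status") %in% names(r)))
        stop(sprintf("result in section '%s' incomplete", nm))
      if (!r$status %in% c("green", "yellow", "red", "not_evaluated"))
        stop(sprintf("invalid status '%s'", r$status))
      if ((r$status == "not_evaluated") != is.null(r$value))
        stop(sprintf("result '%s': value must be absent iff not_evaluated",
                     r$name))
    }
  }
  invisible(TRUE)
}

#' Render a report document
#'
#' Pure function of the document: identical documents render to
#' byte-identical output. JSON is the machine-readable twin (validated
#' against the shipped schema before writing); the text and HTML
#' renderings list Results and Conclusion per section with the
#' traffic-light status, thumbnails referenced last.
#'
#' @param doc a [ReportDocument-class]
#' @param format \code{"json"}, \code{"txt"} or \code{"html"}
#' @param path output file path; NULL returns the rendering as a
#'   character string
#' @return the rendering, invisibly when written to \code{path}
#' @export
renderReport <- function(doc, format = c("json", "txt", "html"),
                         path = NULL) {
  format <- match.arg(format)
  validateReport(doc)
  x <- .reportAsList(doc)
  out <- if (format == "json") {
    as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                  null = "null", pretty = TRUE))
  } else {
    lines <- character(0)
    add <- function(...) lines <<- c(lines, sprintf(...))
    h1 <- function(t) if (format == "html") sprintf("<h2>%s</h2>", t)
      else c(t, strrep("-", nchar(t)))
    if (format == "html")
      lines <- c("<html><body><h1>CT screening report</h1>")
    for (s in x$sections) {
      lines <- c(lines, h1(s$title))
      for (r in s$results) {
        val <- if (is.null(r$value)) "-" else format(r$value)
        row <- sprintf("  %-28s %10s %-6s [%s]%s", r$name, val, r$units,
                       r$status,
                       if (nzchar(r$category_label))
                         paste0(" ", r$category_label) else "")
        lines <- c(lines, if (format == "html")
          sprintf("<p class=\"%s\">%s</p>", r$status, row) else row)
      }
      concl <- sprintf("  Conclusion: %s", s$conclusion)
      lines <- c(lines, if (format == "html")
        sprintf("<p><b>%s</b></p>", concl) else concl, "")
    }
    if (length(x$thumbnails)) {
      lines <- c(lines, h1("Images"),
                 vapply(x$thumbnails, function(t)
                   if (format == "html")
                     sprintf("<img src=\"%s\"/>", t) else
                     sprintf("  %s", t), character(1)))
    }
    if (format == "html") lines <- c(lines, "</body></html>")
    paste(lines, collapse = "\n")
  }
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}
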