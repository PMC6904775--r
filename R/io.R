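#' Read / write observable time-course tables
#'
#' CSV with a mandatory `time` column (hours) plus one column per NMR
#' observable group (uM), optionally a relative `ATP` column; comma
#' separated, '.' decimal, UTF-8, header row mandatory. Reading validates
#' the schema and reports the offending column and row on failure; the
#' write/read pair is lossless to full double precision.
#'
#' @param path file path
#' @param data data.frame as produced by [generateTimeCourse()]
#' @param requiredGroups observable column names that must be present
#' @return the validated data.frame (read), invisibly the path (write)
#' @export
readTimecourseCsv <- function(path,
                              requiredGroups = c("5FU", "FUDR+", "FUMP+",
                                                 "FUDP+FUTP+", "FNA",
                                                 "totalF")) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("missing column: time")
  miss <- setdiff(requiredGroups, names(df))
  if (length(miss)) stop("missing observable column: ",
                         paste(miss, collapse = ", "))
  for (col in c("time", requiredGroups)) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v))
      stop(sprintf("column %s: non-numeric or missing value (first at row %d)",
                   col, which(!is.finite(suppressWarnings(as.numeric(v))))[1]))
    if (col != "time" && any(v < 0))
      stop(sprintf("column %s: negative concentration at row %d",
                   col, which(v < 0)[1]))
  }
  if (is.unsorted(df$time, strictly = TRUE))
    stop("column time: must be strictly increasing")
  df
}

#' @rdname readTimecourseCsv
#' @export
writeTimecourseCsv <- function(data, path) {
  stopifnot("time" %in% names(data))
  utils::write.csv(format(data, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- SBML Level 3 export / import (xml2-based) -----------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
FUMET_NS <- "https://example.org/fumet/sbml"

sbmlId <- function(id) {
  s <- gsub("[^A-Za-z0-9_]", "_", id)
  ifelse(grepl("^[A-Za-z_]", s), s, paste0("sp_", s))
}

# R arithmetic expression -> content MathML string
mathml <- function(e) {
  if (is.numeric(e)) return(sprintf("<cn> %.17g </cn>", e))
  if (is.name(e)) return(sprintf("<ci> %s </ci>", as.character(e)))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(mathml(e[[2]]))
    tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                  "/" = "divide", "^" = "power",
                  stop("unsupported operator in rate expression: ", op))
    args <- vapply(as.list(e)[-1], mathml, character(1))
    return(paste0("<apply> <", tag, "/> ", paste(args, collapse = " "),
                  " </apply>"))
  }
  stop("unsupported rate expression node")
}

rateLawExpression <- function(law, args) {
  tpl <- switch(law,
    irr_mm = "V * %S / (Km + %S)",
    rev_mm = "(Vf * %S / Kms - Vr * %P / Kmp) / (1 + %S / Kms + %P / Kmp)",
    ping_pong = paste(
      "Vf * Vr * (%A * %B - %P * %Q / Keq) /",
      "(Vr * Kmb * %A + Vr * Kma * %B + Vr * %A * %B +",
      "Vf * Kmq * %P / Keq + Vf * Kmp * %Q / Keq + Vf * %P * %Q / Keq +",
      "Vr * Kma * %B * %Q / Kiq + Vf * Kmq * %A * %P / (Kia * Keq))"))
  for (nm in names(args))
    tpl <- gsub(paste0("%", nm), args[[nm]], tpl, fixed = TRUE)
  str2lang(tpl)
}

#' Export a network as SBML Level 3
#'
#' Writes species (with initial concentrations, boundary flags and a
#' fluorination annotation), reactions (reactants/products, reversibility,
#' full kinetic-law MathML with local parameters) and, in a
#' package-namespace annotation, the registry metadata needed for a
#' lossless round trip: rate-law class, parameter group, sharing links,
#' fixed flags and the observable grouping.
#'
#' @param net a [ReactionNetwork-class]
#' @param path output file
#' @return invisibly the path
#' @export
exportSBML <- function(net, path) {
  ids <- speciesIds(net)
  sid <- stats::setNames(sbmlId(ids), ids)
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fumet="%s" level="3" version="2">',
            SBML_NS, FUMET_NS),
    '<model id="fu_metabolism" substanceUnits="micromole" timeUnits="hour">',
    '<annotation><fumet:registry><![CDATA[',
    jsonlite::toJSON(list(links = net@paramLinks, fixed = net@paramFixed,
                          observables = net@observables), digits = NA),
    ']]></fumet:registry></annotation>',
    '<listOfCompartments><compartment id="cell" size="1" constant="true"/></listOfCompartments>',
    "<listOfSpecies>")
  for (i in seq_len(nSpecies(net))) {
    s <- net@species[i, ]
    lines <- c(lines, sprintf(
      '<species id="%s" name="%s" compartment="cell" initialConcentration="%.17g" boundaryCondition="%s" hasOnlySubstanceUnits="false" constant="false" fumet:fluorinated="%s"/>',
      sid[[s$id]], esc(s$id), s$initial, tolower(s$boundary),
      tolower(s$fluorinated)))
  }
  lines <- c(lines, "</listOfSpecies>", "<listOfReactions>")
  pars <- reactionParameters(net)
  for (j in seq_len(nReactions(net))) {
    r <- net@reactions[j, ]
    sub <- r$substrates[[1]]; prod <- r$products[[1]]
    argIds <- switch(r$rateLaw,
      irr_mm = c(S = sid[[sub[1]]]),
      rev_mm = c(S = sid[[sub[1]]], P = sid[[prod[1]]]),
      ping_pong = c(A = sid[[sub[1]]], B = sid[[sub[2]]],
                    P = sid[[prod[1]]], Q = sid[[prod[2]]]))
    lines <- c(lines, sprintf(
      '<reaction id="r%d" name="%s" reversible="%s" fumet:rateLaw="%s" fumet:paramGroup="%s" fumet:hypothetical="%s">',
      r$index, esc(r$ec), tolower(r$rateLaw != "irr_mm"), r$rateLaw,
      r$paramGroup, tolower(r$hypothetical)),
      "<listOfReactants>",
      sprintf('<speciesReference species="%s" stoichiometry="1" constant="true"/>',
              sid[sub]),
      "</listOfReactants>", "<listOfProducts>",
      sprintf('<speciesReference species="%s" stoichiometry="1" constant="true"/>',
              sid[prod]),
      "</listOfProducts>", "<kineticLaw>",
      '<math xmlns="http://www.w3.org/1998/Math/MathML">',
      mathml(rateLawExpression(r$rateLaw, argIds)),
      "</math>", "<listOfLocalParameters>",
      sprintf('<localParameter id="%s" value="%.17g"/>',
              names(pars[[j]]), pars[[j]]),
      "</listOfLocalParameters>", "</kineticLaw>", "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

#' Import a network from SBML written by [exportSBML()]
#' @param path SBML file
#' @return a [ReactionNetwork-class]
#' @export
importSBML <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, f = FUMET_NS)
  spNodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sidToName <- stats::setNames(xml2::xml_attr(spNodes, "name"),
                               xml2::xml_attr(spNodes, "id"))
  species <- data.frame(
    id = unname(sidToName),
    initial = as.numeric(xml2::xml_attr(spNodes, "initialConcentration")),
    fluorinated = xml2::xml_attr(spNodes, "fluorinated") == "true",
    boundary = xml2::xml_attr(spNodes, "boundaryCondition") == "true")
  reg <- jsonlite::fromJSON(xml2::xml_text(
    xml2::xml_find_first(doc, ".//f:registry", ns)))
  rxNodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  paramGroups <- list()
  defs <- lapply(rxNodes, function(nd) {
    grab <- function(xp) unname(sidToName[xml2::xml_attr(
      xml2::xml_find_all(nd, xp, ns), "species")])
    lp <- xml2::xml_find_all(nd, ".//s:localParameter", ns)
    list(index = as.integer(sub("^r", "", xml2::xml_attr(nd, "id"))),
         ec = xml2::xml_attr(nd, "name"),
         rateLaw = xml2::xml_attr(nd, "rateLaw"),
         paramGroup = xml2::xml_attr(nd, "paramGroup"),
         hypothetical = xml2::xml_attr(nd, "hypothetical") == "true",
         substrates = grab(".//s:listOfReactants/s:speciesReference"),
         products = grab(".//s:listOfProducts/s:speciesReference"),
         par = stats::setNames(as.numeric(xml2::xml_attr(lp, "value")),
                               xml2::xml_attr(lp, "id")))
  })
  links <- as.data.frame(reg$links)
  if (!nrow(links)) links <- emptyLinks()
  fixed <- as.data.frame(reg$fixed)
  if (!nrow(fixed)) fixed <- emptyFixed()
  for (d in defs) {
    if (is.null(paramGroups[[d$paramGroup]])) {
      p <- d$par
      # linked slots are stored canonically in their source group
      lk <- links[links$group == d$paramGroup, , drop = FALSE]
      p[lk$name] <- NA_real_
      paramGroups[[d$paramGroup]] <- p
    }
  }
  reactions <- data.frame(
    index = vapply(defs, `[[`, 0L, "index"),
    ec = vapply(defs, `[[`, "", "ec"),
    name = vapply(defs, `[[`, "", "ec"),
    rateLaw = vapply(defs, `[[`, "", "rateLaw"),
    paramGroup = vapply(defs, `[[`, "", "paramGroup"),
    hypothetical = vapply(defs, `[[`, FALSE, "hypothetical"))
  reactions$substrates <- lapply(defs, `[[`, "substrates")
  reactions$products <- lapply(defs, `[[`, "products")
  observables <- lapply(reg$observables, unlist)
  reactionNetwork(species, reactions, paramGroups, links, fixed,
                  observables)
}

# ---- model configuration ---------------------------------------------------

#' Override parameters and initial concentrations from a configuration
#'
#' The configuration is a list with optional elements `parameters` (a list
#' of entries with `reaction` (index) or `group`, `name`, `value`) and
#' `initial` (named species concentrations). [readModelConfig()] loads it
#' from YAML or JSON by file extension.
#'
#' @param net a [ReactionNetwork-class]
#' @param config configuration list
#' @return the modified network
#' @export
applyConfig <- function(net, config) {
  for (p in config$parameters) {
    key <- if (!is.null(p$reaction)) p$reaction else p$group
    net <- setParameter(net, key, p$name, p$value, force = TRUE)
  }
  if (!is.null(config$initial)) {
    ini <- unlist(config$initial)
    bad <- setdiff(names(ini), speciesIds(net))
    if (length(bad)) stop("unknown species in config: ",
                          paste(bad, collapse = ", "))
    net@species$initial[match(names(ini), net@species$id)] <- ini
  }
  net
}

#' @rdname applyConfig
#' @param path YAML (.yaml/.yml) or JSON configuration file
#' @export
readModelConfig <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
}

# ---- plotting ---------------------------------------------------------------

#' Plot observable time courses
#'
#' Base-graphics panel of the six observable groups of a trajectory, with
#' optional observed points overlaid - the standard visual check of a fit.
#'
#' @param traj a [Trajectory-class]
#' @param data optional observed data.frame (time + group columns)
#' @param groups observable columns to draw
#' @export
plotObservables <- function(traj, data = NULL,
                            groups = colnames(traj@observables)) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(groups)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (g in groups) {
    graphics::plot(traj@times, traj@observables[, g], type = "l",
                   xlab = "time [h]", ylab = "concentration [uM]", main = g)
    if (!is.null(data) && g %in% names(data))
      graphics::points(data$time, data[[g]], pch = 16, cex = 0.7)
  }
  invisible(NULL)
}
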