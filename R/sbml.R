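#' SBML Level 3 Version 1 import and export
#'
#' Models are written as SBML L3V1 core: compartments, species (boundary
#' species carry `boundaryCondition="true"`), reactions with
#' reactant/product/modifier lists and a kinetic law whose math is MathML
#' built from the closed-form mechanism expression. The mechanism identity
#' and role binding are preserved in a package annotation so that a model
#' written by this package reads back with native (not opaque) rate laws.
#' Kinetic laws from other tools are parsed from their MathML into an
#' evaluable "foreign" rate law, so imported models still simulate.
#'
#' Serialisation is deterministic: writing, reading and writing again yields
#' byte-identical output.
#'
#' @name sbml-io
NULL

.aakin_ns <- "https://github.com/aakin/ns"

fmt_num <- function(x) {
  # shortest exact decimal representation, stable across platforms
  s <- vapply(x, function(v) {
    for (d in 1:17) {
      cand <- sprintf("%.*g", d, v)
      if (as.numeric(cand) == v) return(cand)
    }
    sprintf("%.17g", v)
  }, "")
  s
}

# ---- MathML ----------------------------------------------------------------

.mathml_ops <- c("+" = "plus", "-" = "minus", "*" = "times",
                 "/" = "divide", "^" = "power")

lang_to_mathml <- function(e) {
  if (is.numeric(e)) return(paste0("<cn> ", fmt_num(e), " </cn>"))
  if (is.name(e)) return(paste0("<ci> ", as.character(e), " </ci>"))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(lang_to_mathml(e[[2]]))
    if (!op %in% names(.mathml_ops))
      stop("cannot serialise operator to MathML: ", op, call. = FALSE)
    args <- vapply(as.list(e)[-1], lang_to_mathml, "")
    return(paste0("<apply><", .mathml_ops[[op]], "/>",
                  paste(args, collapse = ""), "</apply>"))
  }
  stop("cannot serialise expression to MathML", call. = FALSE)
}

mathml_to_lang <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1) stop("malformed MathML <math>", call. = FALSE)
    return(mathml_to_lang(kids[[1]]))
  }
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") {
    type <- xml2::xml_attr(node, "type")
    if (!is.na(type) && type == "e-notation") {
      parts <- xml2::xml_contents(node)
      txt <- trimws(xml2::xml_text(parts[c(1, 3)]))
      return(as.numeric(txt[1]) * 10^as.numeric(txt[2]))
    }
    return(as.numeric(trimws(xml2::xml_text(node))))
  }
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], mathml_to_lang)
    rop <- names(.mathml_ops)[match(op, .mathml_ops)]
    if (is.na(rop)) {
      if (op == "root") rop <- "sqrt"  # minimal extras
      else if (op == "exp") rop <- "exp"
      else if (op == "ln") rop <- "log"
      else stop("unsupported MathML operator: ", op, call. = FALSE)
      return(as.call(c(as.name(rop), args)))
    }
    if (length(args) <= 2) return(as.call(c(as.name(rop), args)))
    # n-ary plus/times fold left
    out <- args[[1]]
    for (a in args[-1]) out <- as.call(list(as.name(rop), out, a))
    return(out)
  }
  stop("unsupported MathML node: ", nm, call. = FALSE)
}

# ---- write -----------------------------------------------------------------

#' Write a kinetic model as SBML L3V1
#'
#' @param model an `aakin_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  x <- function(s) gsub("&", "&amp;", gsub("<", "&lt;", s))
  L <- c('<?xml version="1.0" encoding="UTF-8"?>',
         paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
                ' level="3" version="1">'),
         sprintf('  <model id="%s" substanceUnits="mole" timeUnits="second"' ,
                 if (!is.null(model$annotations$id)) model$annotations$id
                 else "aakin_model"),
         '         extentUnits="mole">')
  ann <- model$annotations
  ann_keys <- names(ann)[vapply(ann, function(a)
    is.character(a) || is.numeric(a), TRUE)]
  if (length(ann_keys)) {
    L <- c(L, "    <annotation>",
           sprintf('      <aakin:meta xmlns:aakin="%s"%s/>', .aakin_ns,
                   paste0(sprintf(' %s="%s"', ann_keys,
                                  vapply(ann[ann_keys], function(a)
                                    x(paste(format(a), collapse = "|")), "")),
                          collapse = "")),
           "    </annotation>")
  }
  L <- c(L, "    <listOfCompartments>")
  for (i in seq_along(model$compartments))
    L <- c(L, sprintf(
      '      <compartment id="%s" spatialDimensions="3" size="%s" constant="true"/>',
      names(model$compartments)[i], fmt_num(model$compartments[[i]])))
  L <- c(L, "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(model$species))) {
    s <- model$species[i, ]
    carb <- if (is.na(s$carbon)) "" else sprintf(' aakin:carbon="%s"',
                                                 fmt_num(s$carbon))
    L <- c(L, sprintf(
      paste0('      <species id="%s" name="%s" compartment="%s"',
             ' initialConcentration="%s" hasOnlySubstanceUnits="false"',
             ' boundaryCondition="%s" constant="false"',
             ' xmlns:aakin="%s"%s/>'),
      s$id, x(s$name), s$compartment, fmt_num(s$initial),
      if (s$fixed) "true" else "false", .aakin_ns, carb))
  }
  L <- c(L, "    </listOfSpecies>", "    <listOfReactions>")
  for (r in model$reactions) {
    L <- c(L, sprintf('      <reaction id="%s" reversible="%s" fast="false">',
                      r$id, if (r$reversible) "true" else "false"))
    if (r$law$mechanism != "foreign")
      L <- c(L, "        <annotation>",
             sprintf('          <aakin:law xmlns:aakin="%s" mechanism="%s" roles="%s"/>',
                     .aakin_ns, r$law$mechanism,
                     paste(names(r$roles), unname(r$roles), sep = "=",
                           collapse = ";")),
             "        </annotation>")
    subs <- r$stoich[r$stoich < 0]; prods <- r$stoich[r$stoich > 0]
    if (length(subs)) {
      L <- c(L, "        <listOfReactants>")
      for (j in seq_along(subs))
        L <- c(L, sprintf(
          '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          names(subs)[j], fmt_num(-subs[[j]])))
      L <- c(L, "        </listOfReactants>")
    }
    if (length(prods)) {
      L <- c(L, "        <listOfProducts>")
      for (j in seq_along(prods))
        L <- c(L, sprintf(
          '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          names(prods)[j], fmt_num(prods[[j]])))
      L <- c(L, "        </listOfProducts>")
    }
    mods <- setdiff(unname(r$roles), names(r$stoich))
    if (length(mods)) {
      L <- c(L, "        <listOfModifiers>")
      for (m in mods)
        L <- c(L, sprintf('          <modifierSpeciesReference species="%s"/>', m))
      L <- c(L, "        </listOfModifiers>")
    }
    expr_str <- if (r$law$mechanism == "foreign")
      r$law$expr_text
    else law_expression(r$law, r$roles,
                        scale_expr = if (r$law$scale == "k") "k"
                        else if ("Vmax" %in% names(r$params) &&
                                 !is.na(r$params["Vmax"])) "Vmax"
                        else "(Kcat * E_total)")
    L <- c(L, "        <kineticLaw>",
           '          <math xmlns="http://www.w3.org/1998/Math/MathML">',
           paste0("            ", lang_to_mathml(str2lang(expr_str))),
           "          </math>")
    if (length(r$params)) {
      L <- c(L, "          <listOfLocalParameters>")
      for (j in seq_along(r$params))
        L <- c(L, sprintf(
          '            <localParameter id="%s" value="%s"/>',
          names(r$params)[j], fmt_num(r$params[[j]])))
      L <- c(L, "          </listOfLocalParameters>")
    }
    L <- c(L, "        </kineticLaw>", "      </reaction>")
  }
  L <- c(L, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(L, path)
  invisible(path)
}

# ---- read ------------------------------------------------------------------

foreign_rate_law <- function(expr_text, param_ids) {
  lang <- str2lang(expr_text)
  structure(list(mechanism = "foreign", roles = character(0),
                 slots = param_ids, scale = "none", reversible = NA,
                 expr_text = expr_text,
                 fn = function(cc, p, V) eval(lang, c(as.list(cc), p))),
            class = "aakin_rate_law")
}

#' Read an SBML kinetic model
#'
#' Accepts SBML Level 2 or Level 3 files with kinetic laws. Reactions
#' written by [write_sbml()] recover their native mechanism from the
#' package annotation; any other MathML becomes an opaque "foreign" rate
#' law that still evaluates numerically (species referenced by id).
#'
#' @param path SBML file.
#' @return an `aakin_model`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::xml_ns_strip(xml2::read_xml(path))
  mod <- xml2::xml_find_first(doc, ".//model")
  comps <- xml2::xml_find_all(mod, ".//listOfCompartments/compartment")
  cvol <- stats::setNames(
    as.numeric(ifelse(is.na(xml2::xml_attr(comps, "size")), 1,
                      xml2::xml_attr(comps, "size"))),
    xml2::xml_attr(comps, "id"))
  sps <- xml2::xml_find_all(mod, ".//listOfSpecies/species")
  num_or <- function(s, d) ifelse(is.na(s), d, suppressWarnings(as.numeric(s)))
  sp_df <- data.frame(
    id = xml2::xml_attr(sps, "id"),
    name = ifelse(is.na(xml2::xml_attr(sps, "name")),
                  xml2::xml_attr(sps, "id"), xml2::xml_attr(sps, "name")),
    compartment = xml2::xml_attr(sps, "compartment"),
    initial = num_or(xml2::xml_attr(sps, "initialConcentration"), 0),
    fixed = xml2::xml_attr(sps, "boundaryCondition") %in% "true",
    carbon = num_or(vapply(sps, function(sn) {
      at <- xml2::xml_attrs(sn)
      i <- match(TRUE, names(at) %in% c("carbon", "aakin:carbon"))
      if (is.na(i)) NA_character_ else unname(at[i])
    }, ""), NA_real_),
    stringsAsFactors = FALSE)

  rx_nodes <- xml2::xml_find_all(mod, ".//listOfReactions/reaction")
  no_law <- character(0)
  reactions <- list()
  for (rn in rx_nodes) {
    rid <- xml2::xml_attr(rn, "id")
    sto <- numeric(0)
    for (sr in xml2::xml_find_all(rn, "./listOfReactants/speciesReference")) {
      sid <- xml2::xml_attr(sr, "species")
      coef <- num_or(xml2::xml_attr(sr, "stoichiometry"), 1)
      sto[sid] <- (if (sid %in% names(sto)) sto[sid] else 0) - coef
    }
    for (sr in xml2::xml_find_all(rn, "./listOfProducts/speciesReference")) {
      sid <- xml2::xml_attr(sr, "species")
      coef <- num_or(xml2::xml_attr(sr, "stoichiometry"), 1)
      sto[sid] <- (if (sid %in% names(sto)) sto[sid] else 0) + coef
    }
    kl <- xml2::xml_find_first(rn, "./kineticLaw")
    if (inherits(kl, "xml_missing")) { no_law <- c(no_law, rid); next }
    lp <- xml2::xml_find_all(
      kl, "./listOfLocalParameters/localParameter | ./listOfParameters/parameter")
    params <- stats::setNames(as.numeric(xml2::xml_attr(lp, "value")),
                              xml2::xml_attr(lp, "id"))
    ann <- xml2::xml_find_first(rn, "./annotation/*[local-name()='law']")
    if (!inherits(ann, "xml_missing")) {
      mech <- xml2::xml_attr(ann, "mechanism")
      role_str <- strsplit(xml2::xml_attr(ann, "roles"), ";", fixed = TRUE)[[1]]
      kv <- strsplit(role_str, "=", fixed = TRUE)
      roles <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
      law <- rate_law(mech)
    } else {
      math <- xml2::xml_find_first(kl, "./math")
      lang <- mathml_to_lang(math)
      syms <- setdiff(all.vars(lang), sp_df$id)
      law <- foreign_rate_law(paste(deparse(lang), collapse = " "), syms)
      ids_used <- intersect(all.vars(lang), sp_df$id)
      roles <- stats::setNames(ids_used, ids_used)
    }
    reactions[[rid]] <- reaction(
      rid, stoich = sto, law = law, roles = roles, params = params,
      reversible = xml2::xml_attr(rn, "reversible") %in% "true")
  }
  if (length(no_law))
    stop("missing kinetic law for reaction(s): ",
         paste(no_law, collapse = ", "), call. = FALSE)

  ann <- list()
  meta <- xml2::xml_find_first(mod, "./annotation/*[local-name()='meta']")
  if (!inherits(meta, "xml_missing")) {
    at <- xml2::xml_attrs(meta)
    at <- at[!grepl("xmlns", names(at))]
    ann <- as.list(at)
    num <- suppressWarnings(vapply(ann, function(a)
      !is.na(as.numeric(a)), TRUE))
    ann[num] <- lapply(ann[num], as.numeric)
  }
  if (!"cytosol" %in% names(cvol)) cvol <- c(cvol, cytosol = 1)
  if (!"extracellular" %in% names(cvol)) cvol <- c(cvol, extracellular = 1)
  # foreign models may use other compartment names; map species onto the
  # two-compartment convention by flagging non-cytosol as extracellular only
  # when declared so
  sp_df$compartment[!sp_df$compartment %in% c("cytosol", "extracellular")] <-
    "cytosol"
  kinetic_model(sp_df, reactions,
                compartments = cvol[c("cytosol", "extracellular")],
                annotations = ann)
}
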