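#' Assemble and validate a taxon trait table
#'
#' A trait table couples per-taxon biology (diet fractions, agility, defenses,
#' vertical stratum, allometric coefficients) with the basal resource nodes of
#' the food web. All downstream stages — community building, diet-matrix
#' construction, flux calculation — consume a validated `trait_table`.
#'
#' Required columns of `taxa`:
#' \describe{
#'   \item{taxon_id}{unique short name}
#'   \item{fauna_class}{one of `"macrofauna"`, `"mesofauna"`, `"nematode"`}
#'   \item{frac_animal, frac_plant, frac_microbe, frac_detritus}{diet
#'     proportions in \[0, 1\]; their sum must lie in (0, 1\] — a pure basal
#'     resource is a resource node, not a taxon}
#'   \item{agility}{prey agility score in \[0, 1\] (1 = highly agile)}
#'   \item{defended}{logical; physical or chemical defenses}
#'   \item{stratum}{`"epigeic"`, `"hemiedaphic"` or `"euedaphic"`}
#'   \item{metab_ln_x0, metab_a, metab_E}{metabolic regression coefficients
#'     (intercept on ln scale, mass exponent, activation energy in eV)}
#'   \item{lw_form, lw_a, lw_b}{length–mass regression: `lw_form` is
#'     `"power"` (M = a L^b), `"length_width"` (M = a (L W^2)^b, widths
#'     required) or `"log10"` (log10 M = a + b log10 L); `NA` when
#'     `fixed_body_mass` is used instead}
#'   \item{fixed_body_mass}{mass in mg taken from a reference table rather than
#'     measurement (nematodes); `NA` when a regression is used}
#' }
#'
#' Exactly one of \{regression, fixed mass\} must be usable per taxon.
#'
#' @param taxa data frame of per-taxon traits (see Details).
#' @param resources data frame of basal nodes with columns `node_id`,
#'   `resource_type` (`"plant"`, `"microbe"` or `"detritus"`) and optionally
#'   `pool_biomass` (mg per mesocosm; only needed when basal preferences are
#'   biomass-scaled). Defaults to one node per resource type.
#' @return An object of class `trait_table`: a list with tibbles `taxa` and
#'   `resources`.
#' @export
#' @examples
#' tr <- trait_table(tibble::tibble(
#'   taxon_id = "collembola1", fauna_class = "mesofauna",
#'   frac_animal = 0, frac_plant = 0, frac_microbe = 0.5, frac_detritus = 0.5,
#'   agility = 0.6, defended = FALSE, stratum = "hemiedaphic",
#'   metab_ln_x0 = 23.055, metab_a = 0.695, metab_E = 0.686,
#'   lw_form = "power", lw_a = 0.08, lw_b = 2.5, fixed_body_mass = NA
#' ))
#' tr$resources
trait_table <- function(taxa, resources = default_resources()) {
  taxa <- tibble::as_tibble(taxa)
  resources <- tibble::as_tibble(resources)

  req <- c("taxon_id", "fauna_class", "frac_animal", "frac_plant",
           "frac_microbe", "frac_detritus", "agility", "defended", "stratum",
           "metab_ln_x0", "metab_a", "metab_E",
           "lw_form", "lw_a", "lw_b", "fixed_body_mass")
  missing_cols <- setdiff(req, names(taxa))
  if (length(missing_cols) > 0) {
    abort(paste0("trait table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(taxa$taxon_id)) {
    dup <- unique(taxa$taxon_id[duplicated(taxa$taxon_id)])
    abort(paste0("duplicated taxon_id: ", paste(dup, collapse = ", ")))
  }
  bad_class <- !taxa$fauna_class %in% .fauna_classes
  if (any(bad_class)) {
    abort(paste0("unknown fauna_class for taxon ",
                 paste(taxa$taxon_id[bad_class], collapse = ", ")))
  }
  bad_stratum <- !taxa$stratum %in% .strata
  if (any(bad_stratum)) {
    abort(paste0("unknown stratum for taxon ",
                 paste(taxa$taxon_id[bad_stratum], collapse = ", ")))
  }

  fr <- as.matrix(taxa[paste0("frac_", .diet_components)])
  out_of_bounds <- rowSums(is.na(fr) | fr < 0 | fr > 1) > 0
  if (any(out_of_bounds)) {
    abort(paste0("diet fraction outside [0, 1] for taxon ",
                 paste(taxa$taxon_id[out_of_bounds], collapse = ", ")))
  }
  s <- rowSums(fr)
  bad_sum <- s <= 0 | s > 1 + 1e-9
  if (any(bad_sum)) {
    abort(paste0("diet fractions must sum in (0, 1] for taxon ",
                 paste(taxa$taxon_id[bad_sum], collapse = ", ")))
  }
  bad_agi <- is.na(taxa$agility) | taxa$agility < 0 | taxa$agility > 1
  if (any(bad_agi)) {
    abort(paste0("agility outside [0, 1] for taxon ",
                 paste(taxa$taxon_id[bad_agi], collapse = ", ")))
  }

  has_reg <- !is.na(taxa$lw_form)
  has_fix <- !is.na(taxa$fixed_body_mass)
  bad_mass <- !xor(has_reg, has_fix)
  if (any(bad_mass)) {
    abort(paste0("exactly one of {length-mass regression, fixed_body_mass} ",
                 "must be given for taxon ",
                 paste(taxa$taxon_id[bad_mass], collapse = ", ")))
  }
  bad_form <- has_reg & !taxa$lw_form %in% c("power", "length_width", "log10")
  if (any(bad_form)) {
    abort(paste0("unknown lw_form for taxon ",
                 paste(taxa$taxon_id[bad_form], collapse = ", ")))
  }
  if (any(has_fix & taxa$fixed_body_mass <= 0)) {
    abort("fixed_body_mass must be positive")
  }

  rreq <- c("node_id", "resource_type")
  rmiss <- setdiff(rreq, names(resources))
  if (length(rmiss) > 0) {
    abort(paste0("resource table is missing column(s): ",
                 paste(rmiss, collapse = ", ")))
  }
  if (!"pool_biomass" %in% names(resources)) resources$pool_biomass <- NA_real_
  if (anyDuplicated(resources$node_id)) abort("duplicated resource node_id")
  bad_rt <- !resources$resource_type %in% .resource_types
  if (any(bad_rt)) {
    abort(paste0("unknown resource_type for node ",
                 paste(resources$node_id[bad_rt], collapse = ", ")))
  }
  clash <- intersect(resources$node_id, taxa$taxon_id)
  if (length(clash) > 0) {
    abort(paste0("node_id clashes with taxon_id: ",
                 paste(clash, collapse = ", ")))
  }

  structure(list(taxa = taxa, resources = resources), class = "trait_table")
}

#' Default basal resource nodes: one pool per resource type
#'
#' @param pool_biomass optional named numeric vector of standing biomasses
#'   (mg per mesocosm) for `plant`, `microbe`, `detritus`; `NA` (the default)
#'   leaves basal preferences unweighted by pool size.
#' @return tibble with columns `node_id`, `resource_type`, `pool_biomass`.
#' @export
default_resources <- function(pool_biomass = NULL) {
  pb <- rep(NA_real_, 3)
  names(pb) <- .resource_types
  if (!is.null(pool_biomass)) pb[names(pool_biomass)] <- pool_biomass
  tibble::tibble(
    node_id = .resource_types,
    resource_type = .resource_types,
    pool_biomass = unname(pb)
  )
}

#' @export
print.trait_table <- function(x, ...) {
  cat("<trait_table> ", nrow(x$taxa), " taxa, ",
      nrow(x$resources), " basal nodes\n", sep = "")
  print(dplyr::count(x$taxa, .data$fauna_class))
  invisible(x)
}

#' Read / write trait tables as delimited text
#'
#' `read_trait_table()` reads the taxon CSV (and optionally a resource-node
#' CSV) written by `write_trait_table()`; values round-trip exactly.
#'
#' @param path path of the taxon CSV.
#' @param resources_path optional path of the resource-node CSV; when `NULL`
#'   the default one-node-per-type pools are used.
#' @return A validated [trait_table()].
#' @export
read_trait_table <- function(path, resources_path = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  taxa <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            taxon_id = "c", fauna_class = "c", stratum = "c",
                            lw_form = "c", defended = "l",
                            .default = readr::col_double()))
  resources <- if (is.null(resources_path)) {
    default_resources()
  } else {
    readr::read_csv(resources_path, show_col_types = FALSE,
                    col_types = readr::cols(node_id = "c", resource_type = "c",
                                            .default = readr::col_double()))
  }
  trait_table(taxa, resources)
}

#' @rdname read_trait_table
#' @param traits a `trait_table`.
#' @export
write_trait_table <- function(traits, path, resources_path = NULL) {
  stopifnot(inherits(traits, "trait_table"))
  readr::write_csv(traits$taxa, path)
  if (!is.null(resources_path)) readr::write_csv(traits$resources, resources_path)
  invisible(path)
}

#' Check that sampled taxa are covered by a trait table
#'
#' @param traits a [trait_table()].
#' @param sample_taxa character vector of taxon ids appearing in sample
#'   records.
#' @return Character vector of sampled taxa absent from the table (empty when
#'   consistent).
#' @export
validate_against_samples <- function(traits, sample_taxa) {
  stopifnot(inherits(traits, "trait_table"))
  setdiff(unique(sample_taxa), traits$taxa$taxon_id)
}

#' Vertical stratification overlap matrix
#'
#' Encounter weighting between predator and prey strata: 1 within a stratum,
#' `adjacent` between neighbouring strata (epigeic–hemiedaphic,
#' hemiedaphic–euedaphic), 0 between epigeic and euedaphic.
#'
#' @param adjacent overlap weight between adjacent strata (default 0.5).
#' @return 3x3 numeric matrix with dimnames `epigeic`, `hemiedaphic`,
#'   `euedaphic`.
#' @export
stratum_overlap <- function(adjacent = 0.5) {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- adjacent
  m[2, 3] <- m[3, 2] <- adjacent
  dimnames(m) <- list(.strata, .strata)
  m
}
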