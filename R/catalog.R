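#' The eight quality-of-care domains
#'
#' Fixed set of domain keys used by the indicator catalog, in catalog order,
#' with human-readable labels. The domain-weighted additive index equalises
#' influence across exactly these eight domains.
#'
#' @return A tibble with columns `domain` (key) and `label`.
#' @export
qoc_domains <- function() {
  tibble(
    domain = c("choice_of_methods", "constellation_of_services", "management",
               "infrastructure", "technical_competence", "follow_up",
               "information_to_client", "client_provider_relations"),
    label = c("Choice of methods", "Constellation of services", "Management",
              "Infrastructure", "Technical/provider competence", "Follow-up",
              "Information given to client", "Client-provider relations")
  )
}

catalog_rules <- c("direct", "mean_dichotomize", "concordance",
                   "method_mix", "quality_assurance")
catalog_levels <- c("facility", "provider", "client")

# One row per indicator; source_fields is a semicolon-joined list of the raw
# survey columns its construction rule consumes.
catalog_row <- function(id, label, domain, donabedian, source_level, rule,
                        source_fields) {
  tibble(id = id, label = label, domain = domain, donabedian = donabedian,
         source_level = source_level, rule = rule,
         source_fields = paste(source_fields, collapse = ";"))
}

#' The packaged default indicator catalog
#'
#' Fifty-three binary quality-of-care indicators for family planning services
#' in eight domains, following the Donabedian structure/process framing.
#' Structure indicators come from the facility inventory; process indicators
#' from client-visit observations and exit interviews (three of them require
#' concordance between the two); one structure indicator (recent training)
#' comes from the provider interview.
#'
#' Domain sizes: choice of methods 3, constellation of services 5,
#' management 6, infrastructure 17, technical/provider competence 15,
#' follow-up 1, information given to client 2, client-provider relations 4.
#'
#' @return A validated `qoc_catalog` tibble with columns `id`, `label`,
#'   `domain`, `donabedian`, `source_level`, `rule`, `source_fields`.
#' @seealso [read_catalog()], [write_catalog()], [validate_catalog()]
#' @export
#' @examples
#' cat53 <- default_catalog()
#' nrow(cat53)            # 53
#' dplyr::count(cat53, domain)
default_catalog <- function() {
  rows <- list(
    ## choice of methods (3)
    catalog_row("method_mix", "Mix of methods provided (short-acting, long-acting/permanent, barrier)",
                "choice_of_methods", "structure", "facility", "method_mix",
                c("has_pill", "has_injectable", "has_implant", "has_iud",
                  "has_sterilization", "has_condom")),
    catalog_row("mentioned_methods", "Provider mentioned two or more methods",
                "choice_of_methods", "process", "client", "mean_dichotomize",
                "obs_mentioned_methods"),
    catalog_row("asked_method_choice", "Provider asked about client's method of choice",
                "choice_of_methods", "process", "client", "mean_dichotomize",
                "obs_asked_method_choice"),
    ## constellation of services (5)
    catalog_row("svc_anc", "ANC services available", "constellation_of_services",
                "structure", "facility", "direct", "svc_anc"),
    catalog_row("svc_pnc", "PNC services available", "constellation_of_services",
                "structure", "facility", "direct", "svc_pnc"),
    catalog_row("svc_sti", "STI services available", "constellation_of_services",
                "structure", "facility", "direct", "svc_sti"),
    catalog_row("svc_hct", "HIV counselling and testing available", "constellation_of_services",
                "structure", "facility", "direct", "svc_hct"),
    catalog_row("svc_pmtct", "PMTCT services available", "constellation_of_services",
                "structure", "facility", "direct", "svc_pmtct"),
    ## management (6)
    catalog_row("mgmt_review_system", "System for reviewing management/administrative issues",
                "management", "structure", "facility", "direct", "mgmt_review_system"),
    catalog_row("mgmt_client_opinion", "System to obtain client opinions",
                "management", "structure", "facility", "direct", "mgmt_client_opinion"),
    catalog_row("mgmt_supervision", "External supervision in the last 6 months",
                "management", "structure", "facility", "direct", "mgmt_supervision"),
    catalog_row("mgmt_inventory", "Inventory of contraceptive supplies",
                "management", "structure", "facility", "direct", "mgmt_inventory"),
    catalog_row("mgmt_stock_by_expiry", "Contraceptive stock organized by expiration date",
                "management", "structure", "facility", "direct", "mgmt_stock_by_expiry"),
    catalog_row("mgmt_protected_stock", "Contraceptives protected from water, sun, pests",
                "management", "structure", "facility", "direct", "mgmt_protected_stock"),
    ## infrastructure, general (6 incl. quality assurance composite)
    catalog_row("infra_electricity", "Electricity", "infrastructure", "structure",
                "facility", "direct", "infra_electricity"),
    catalog_row("infra_water", "Improved water source", "infrastructure", "structure",
                "facility", "direct", "infra_water"),
    catalog_row("infra_toilet", "Functional client toilet", "infrastructure", "structure",
                "facility", "direct", "infra_toilet"),
    catalog_row("infra_telephone", "Telephone or short-wave radio", "infrastructure", "structure",
                "facility", "direct", "infra_telephone"),
    catalog_row("infra_waiting_area", "Protected waiting area", "infrastructure", "structure",
                "facility", "direct", "infra_waiting_area"),
    catalog_row("quality_assurance", "Quality assurance measures in place (documented)",
                "infrastructure", "structure", "facility", "quality_assurance",
                c("qa_meeting_minutes", "qa_supervisory_checklist",
                  "qa_mortality_review", "qa_record_audit")),
    ## infrastructure, family planning area (11)
    catalog_row("fp_five_days", "Family planning services provided 5 days per week",
                "infrastructure", "structure", "facility", "direct", "fp_five_days"),
    catalog_row("fp_private_room", "Private exam room", "infrastructure", "structure",
                "facility", "direct", "fp_private_room"),
    catalog_row("fp_bp_apparatus", "Blood pressure apparatus (digital, or cuff and stethoscope)",
                "infrastructure", "structure", "facility", "direct", "fp_bp_apparatus"),
    catalog_row("fp_speculum", "Speculum", "infrastructure", "structure",
                "facility", "direct", "fp_speculum"),
    catalog_row("fp_guidelines", "Family planning guidelines", "infrastructure", "structure",
                "facility", "direct", "fp_guidelines"),
    catalog_row("fp_table_stool", "Exam table and stool", "infrastructure", "structure",
                "facility", "direct", "fp_table_stool"),
    catalog_row("fp_light", "Exam light", "infrastructure", "structure",
                "facility", "direct", "fp_light"),
    catalog_row("fp_soap", "Soap", "infrastructure", "structure",
                "facility", "direct", "fp_soap"),
    catalog_row("fp_gloves", "Latex gloves", "infrastructure", "structure",
                "facility", "direct", "fp_gloves"),
    catalog_row("fp_decontamination", "Decontamination solution", "infrastructure", "structure",
                "facility", "direct", "fp_decontamination"),
    catalog_row("fp_sharps_box", "Sharps box", "infrastructure", "structure",
                "facility", "direct", "fp_sharps_box"),
    ## technical / provider competence (15)
    catalog_row("client_card", "Client card used during visit", "technical_competence",
                "process", "client", "mean_dichotomize", "obs_client_card"),
    catalog_row("fp_training", "Recent training in family planning provision",
                "technical_competence", "structure", "provider", "mean_dichotomize",
                "prov_fp_training"),
    catalog_row("hist_last_delivery", "Last delivery date assessed", "technical_competence",
                "process", "client", "mean_dichotomize", "obs_last_delivery"),
    catalog_row("hist_pregnancy", "Pregnancy status assessed", "technical_competence",
                "process", "client", "mean_dichotomize", "obs_pregnancy_status"),
    catalog_row("hist_breastfeeding", "Breastfeeding status assessed", "technical_competence",
                "process", "client", "mean_dichotomize", "obs_breastfeeding"),
    catalog_row("hist_menstrual", "Menstrual cycle regularity assessed", "technical_competence",
                "process", "client", "mean_dichotomize", "obs_menstrual_cycle"),
    catalog_row("intent_age", "Age of client assessed", "technical_competence",
                "process", "client", "mean_dichotomize", "obs_age_assessed"),
    catalog_row("intent_children", "Current number of children assessed", "technical_competence",
                "process", "client", "mean_dichotomize", "obs_num_children"),
    catalog_row("intent_desire_more", "Desire for more children assessed", "technical_competence",
                "process", "client", "mean_dichotomize", "obs_desire_more_children"),
    catalog_row("intent_timing", "Desired timing of next child assessed", "technical_competence",
                "process", "client", "mean_dichotomize", "obs_timing_next_child"),
    catalog_row("health_bp", "Blood pressure measured", "technical_competence",
                "process", "client", "mean_dichotomize", "obs_blood_pressure"),
    catalog_row("health_weight", "Weight measured", "technical_competence",
                "process", "client", "mean_dichotomize", "obs_weight"),
    catalog_row("health_smoking", "Smoking habits assessed", "technical_competence",
                "process", "client", "mean_dichotomize", "obs_smoking"),
    catalog_row("health_sti", "STI symptoms assessed", "technical_competence",
                "process", "client", "mean_dichotomize", "obs_sti_symptoms"),
    catalog_row("health_chronic", "Chronic illnesses assessed", "technical_competence",
                "process", "client", "mean_dichotomize", "obs_chronic_illness"),
    ## follow-up (1), concordance between observation and exit interview
    catalog_row("told_return", "Provider informed client when to return",
                "follow_up", "process", "client", "concordance",
                c("obs_told_return", "exit_told_return")),
    ## information given to client (2), concordance
    catalog_row("explained_use", "Provider explains how to use the selected method",
                "information_to_client", "process", "client", "concordance",
                c("obs_explained_use", "exit_explained_use")),
    catalog_row("side_effects", "Provider explains side effects of selected method",
                "information_to_client", "process", "client", "concordance",
                c("obs_side_effects", "exit_side_effects")),
    ## client-provider relations (4)
    catalog_row("treated_well", "Staff treated client very well", "client_provider_relations",
                "process", "client", "mean_dichotomize", "cx_treated_well"),
    catalog_row("asked_questions", "Provider asked if client had questions",
                "client_provider_relations", "process", "client", "mean_dichotomize",
                "cx_asked_questions"),
    catalog_row("comfortable", "Client felt comfortable asking questions",
                "client_provider_relations", "process", "client", "mean_dichotomize",
                "cx_comfortable"),
    catalog_row("confidentiality", "Provider assured client of confidentiality",
                "client_provider_relations", "process", "client", "mean_dichotomize",
                "cx_confidentiality")
  )
  out <- bind_rows(rows)
  class(out) <- c("qoc_catalog", class(out))
  validate_catalog(out)
}

#' Validate an indicator catalog
#'
#' Checks structural invariants: unique ids, domains drawn from the fixed
#' eight-domain set, known construction rules, and rule-specific field arity
#' (concordance needs an observation/exit pair; method mix six stock flags;
#' quality assurance four documented-activity flags; direct indicators must be
#' facility-level).
#'
#' @param catalog A data frame with the catalog columns.
#' @return The catalog, invisibly classed as `qoc_catalog`, or an error
#'   naming the offending row(s).
#' @export
validate_catalog <- function(catalog) {
  catalog <- as_tibble(catalog)
  stopifnot_cols(catalog, c("id", "label", "domain", "donabedian",
                            "source_level", "rule", "source_fields"),
                 "indicator catalog")
  dup <- catalog$id[duplicated(catalog$id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate indicator id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  bad_dom <- catalog$id[!catalog$domain %in% qoc_domains()$domain]
  if (length(bad_dom) > 0) {
    abort(sprintf("unknown domain for indicator(s): %s", paste(bad_dom, collapse = ", ")))
  }
  bad_rule <- catalog$id[!catalog$rule %in% catalog_rules]
  if (length(bad_rule) > 0) {
    abort(sprintf("unknown rule for indicator(s): %s", paste(bad_rule, collapse = ", ")))
  }
  bad_lvl <- catalog$id[!catalog$source_level %in% catalog_levels]
  if (length(bad_lvl) > 0) {
    abort(sprintf("unknown source level for indicator(s): %s", paste(bad_lvl, collapse = ", ")))
  }
  nf <- lengths(strsplit(catalog$source_fields, ";", fixed = TRUE))
  arity_bad <- (catalog$rule == "concordance" & nf != 2L) |
    (catalog$rule == "method_mix" & nf != 6L) |
    (catalog$rule == "quality_assurance" & nf != 4L) |
    (catalog$rule %in% c("direct", "mean_dichotomize") & nf != 1L)
  if (any(arity_bad)) {
    abort(sprintf("wrong source-field arity for indicator(s): %s",
                  paste(catalog$id[arity_bad], collapse = ", ")))
  }
  lvl_bad <- catalog$rule %in% c("direct", "method_mix", "quality_assurance") &
    catalog$source_level != "facility"
  if (any(lvl_bad)) {
    abort(sprintf("rule requires facility source level for indicator(s): %s",
                  paste(catalog$id[lvl_bad], collapse = ", ")))
  }
  if (!inherits(catalog, "qoc_catalog")) {
    class(catalog) <- c("qoc_catalog", class(catalog))
  }
  invisible(catalog)
}

#' Read an indicator catalog from CSV, or get the packaged default
#'
#' @param path Path to a catalog CSV with the columns of [default_catalog()],
#'   or the token `"default"` for the packaged 53-indicator catalog.
#' @return A validated `qoc_catalog` tibble.
#' @export
read_catalog <- function(path = "default") {
  if (identical(path, "default")) return(default_catalog())
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  validate_catalog(df)
  out <- as_tibble(df)
  class(out) <- c("qoc_catalog", class(out))
  out
}

#' Write an indicator catalog to CSV
#'
#' The written file round-trips losslessly through [read_catalog()].
#'
#' @param catalog A `qoc_catalog` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  readr::write_csv(as_tibble(catalog), path, progress = FALSE)
  invisible(path)
}

# split the source_fields column into a list of character vectors
catalog_fields <- function(catalog) {
  strsplit(catalog$source_fields, ";", fixed = TRUE)
}

# every raw field a catalog consumes, by source level
catalog_raw_fields <- function(catalog, level) {
  unique(unlist(catalog_fields(catalog[catalog$source_level == level, ])))
}
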