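# Template sets for synthetic pathology findings. Narrative filler is written
# so that it never matches any extraction pattern (linted by
# lint_template_set(); enforced in the test suite): clean-corpus accuracy then
# measures the rules alone, not template luck.

#' Retrieve a finding template set
#'
#' Synthetic findings are assembled from slot-wise sentence variants: clinical
#' information, macroscopy, microscopy, a neoadjuvant-status sentence, the
#' ICD-10 localization line, the TNM formula line and an assessment. `"de"`
#' is the default German-style set; `"en"` is an English alternative;
#' `"de_alt"` shares the narrative slots with `"de"` but phrases the
#' neoadjuvant status with disjoint wording, which makes it a novel template
#' variant for feedback-retraining experiments.
#'
#' @param id one of `"de"`, `"en"`, `"de_alt"`.
#' @return named list of character vectors (sentence variants per slot) plus
#'   the two label strings.
#' @export
template_set <- function(id = "de") {
  de <- list(
    clinical = c(
      "Klinische Angaben: Hemikolektomiepraeparat bei bekanntem Adenokarzinom.",
      "Klinische Angaben: Rektumresektat nach tiefer anteriorer Resektion.",
      "Klinische Angaben: Sigmaresektat bei stenosierendem Tumor.",
      "Klinische Angaben: Kolonsegmentresektat, endoskopisch gesicherte Neoplasie."
    ),
    macro = c(
      "Makroskopie: Das Resektat misst etwa zwanzig Zentimeter, zentral ein ulzerierter Tumor.",
      "Makroskopie: Darmsegment mit derbem, die Wand infiltrierendem Tumor von vier Zentimetern.",
      "Makroskopie: Exophytisch wachsender Tumor mit zentraler Einsenkung, Absetzungsraender makroskopisch frei.",
      "Makroskopie: Schleimhaut mit polypoidem Tumor, umgebendes Fettgewebe unauffaellig."
    ),
    micro = c(
      "Mikroskopie: Maessig differenziertes Adenokarzinom mit Infiltration der Muscularis propria.",
      "Mikroskopie: Gering differenziertes Adenokarzinom, herdfoermig muzinoese Differenzierung.",
      "Mikroskopie: Adenokarzinom vom intestinalen Typ, deutliche desmoplastische Stromareaktion.",
      "Mikroskopie: Invasives Adenokarzinom, angrenzend tubulovilloeses Adenom mit hochgradiger Dysplasie."
    ),
    neo_pos = c(
      "Zustand nach neoadjuvanter Radiochemotherapie, deutliche regressive Veraenderungen.",
      "Nach neoadjuvanter Radiochemotherapie zeigt sich ein ausgepraegtes Regressionsgrading."
    ),
    neo_neg = c(
      "Keine Vorbehandlung bekannt.",
      "Ohne vorausgegangene onkologische Vorbehandlung."
    ),
    assessment = c(
      "Beurteilung: Die Befunde entsprechen einem kolorektalen Karzinom, Klassifikation siehe oben.",
      "Beurteilung: Karzinom des Dickdarms, Stadierung wie angegeben.",
      "Beurteilung: Kolorektales Karzinom, weitere Angaben siehe Klassifikation."
    ),
    loc_label = "Tumorlokalisation (ICD-10): ",
    tnm_label = "TNM-Klassifikation: "
  )

  en <- list(
    clinical = c(
      "Clinical information: hemicolectomy specimen, known adenocarcinoma.",
      "Clinical information: rectal resection specimen after low anterior resection.",
      "Clinical information: sigmoid resection for an obstructing tumor."
    ),
    macro = c(
      "Gross description: the specimen measures about twenty centimeters with a central ulcerated tumor.",
      "Gross description: bowel segment with a firm tumor infiltrating the wall.",
      "Gross description: exophytic tumor, resection margins grossly free."
    ),
    micro = c(
      "Microscopy: moderately differentiated adenocarcinoma infiltrating the muscularis propria.",
      "Microscopy: poorly differentiated adenocarcinoma with focal mucinous differentiation.",
      "Microscopy: invasive adenocarcinoma of intestinal type."
    ),
    neo_pos = c(
      "Status post neoadjuvant radiochemotherapy with marked regressive changes.",
      "After neoadjuvant radiochemotherapy there is pronounced tumor regression."
    ),
    neo_neg = c(
      "No pretreatment reported.",
      "Without any preceding oncologic pretreatment."
    ),
    assessment = c(
      "Assessment: findings consistent with colorectal carcinoma, classification as above.",
      "Assessment: carcinoma of the large bowel, staging as stated."
    ),
    loc_label = "Tumor localization (ICD-10): ",
    tnm_label = "TNM classification: "
  )

  de_alt <- de
  de_alt$neo_pos <- c(
    "Status nach praeoperativer Vorbehandlung mittels kombinierter Bestrahlung und Zytostatikagabe.",
    "Praeoperative Vorbehandlung durch Bestrahlung erfolgt, regressive Tumorveraenderungen."
  )
  de_alt$neo_neg <- c(
    "Eine praeoperative Vorbehandlung erfolgte nicht.",
    "Keinerlei praeoperative Bestrahlung oder Zytostatikagabe erfolgt."
  )

  switch(id,
    de = de, en = en, de_alt = de_alt,
    stop("unknown template set: ", id, call. = FALSE)
  )
}

#' Lint a template set against the extraction patterns
#'
#' Checks that no narrative sentence variant of a template set matches any
#' rule-based extraction pattern (staging tokens, lymph-node fraction,
#' ICD-10 code). Guarantees that on a clean corpus every pattern hit comes
#' from the rendered formula/localization lines.
#'
#' @param id template set identifier.
#' @return invisibly `TRUE`; errors with the offending sentence otherwise.
#' @export
lint_template_set <- function(id = "de") {
  tpl <- template_set(id)
  sentences <- unlist(tpl[c("clinical", "macro", "micro", "neo_pos",
                            "neo_neg", "assessment")], use.names = FALSE)
  patterns <- c(vapply(feature_specs(), `[[`, "", "pattern"),
                .FRACTION_PATTERN, .FRACTION_FALLBACK, .ICD_PATTERN)
  for (s in sentences) {
    for (p in patterns) {
      if (nrow(match_pattern(s, p)) > 0L) {
        stop(sprintf("template sentence matches extraction pattern %s: '%s'", p, s),
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}
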