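#' Worked toy examples
#'
#' Constructs, in code, the small fixtures used throughout the
#' documentation and tests:
#'
#' * `"table3"` -- the sentence *"A thrombocyte is a kind of blood cell"*
#'   and a six-class toy ontology (acronym SNOMEDCT) that yields exactly six
#'   annotations, two of which survive overlap resolution for a raw
#'   coverage of 31 points.
#' * `"table4"` / `"table5"` -- the sentence *"Penicillin is an antibiotic
#'   used to treat tonsillitis"* and two ontologies: O1 (declared size
#'   120,000) matching *penicillin* (PREF, depth 5; 1 definition, 2
#'   synonyms, 7 properties) and *antibiotic* (SYN, depth 3; 1/7/16), and
#'   O2 (declared size 800) matching *penicillin* (SYN, depth 6; 0/1/3) and
#'   *tonsillitis* (PREF, depth 12; 0/0/2). Both names return the same
#'   bundle: the class-detail counts and the sizes/depths describe the same
#'   two ontologies.
#'
#' @param name `"table3"`, `"table4"`, `"table5"`, or `"all"`.
#' @return A list with elements `doc` (an [input_document()]), `ontologies`
#'   (named list), `metadata` (a small [repository_metadata()]) and
#'   `config`; for `"all"`, a named list of such bundles.
#' @export
#' @examples
#' fx <- worked_examples("table3")
#' annotate(fx$doc, fx$ontologies)
worked_examples <- function(name = c("table3", "table4", "table5", "all")) {
  name <- match.arg(name)
  if (name == "all") {
    return(list(table3 = fixture_table3(), table4 = fixture_table45(),
                table5 = fixture_table45()))
  }
  if (name == "table3") fixture_table3() else fixture_table45()
}

fixture_table3 <- function() {
  snomed <- ontology(tibble::tibble(
    id = c("SCT:PLT", "SCT:BC", "SCT:BLOOD", "SCT:CS", "SCT:CELL", "SCT:EC"),
    pref_label = c("platelet", "blood cell", "blood", "cell structure",
                   "cell", "entire cell"),
    synonyms = c("thrombocyte", "", "", "cell", "", "cell"),
    definition_count = c(1L, 1L, 1L, 0L, 1L, 0L),
    property_count = c(4L, 6L, 8L, 2L, 9L, 1L)
  ), acronym = "SNOMEDCT")
  list(doc = input_document("A thrombocyte is a kind of blood cell"),
       ontologies = list(SNOMEDCT = snomed),
       metadata = fixture_metadata(c("SNOMEDCT")),
       config = recommender_config())
}

fixture_table45 <- function() {
  # ancestor chains give penicillin depth 5 / antibiotic depth 3 in O1,
  # penicillin depth 6 / tonsillitis depth 12 in O2; ancestor labels use
  # words absent from the example sentence so they never match
  o1_anc <- tibble::tibble(
    id = paste0("O1:A", 1:4),
    pref_label = c("medicinal product", "drug category",
                   "chemical substance", "organic compound"),
    synonyms = "", definition_count = 0L, property_count = 0L,
    parents = c("", paste0("O1:A", 1:3))
  )
  o1 <- ontology(dplyr::bind_rows(o1_anc, tibble::tibble(
    id = c("O1:PCN", "O1:ABX"),
    pref_label = c("penicillin", "antibacterial agent"),
    synonyms = c("penicillin G|benzylpenicillin",
                 paste(c("antibiotic", "antibiotics", "antibacterial",
                         "anti-bacterial", "antimicrobial agent",
                         "bacteriocide", "antibiotic drug"), collapse = "|")),
    definition_count = c(1L, 1L),
    property_count = c(7L, 16L),
    parents = c("O1:A4", "O1:A2")
  )), acronym = "O1", declared_size = 120000)

  o2_anc <- tibble::tibble(
    id = paste0("O2:B", 1:11),
    pref_label = paste("intermediate concept", c(
      "one", "two", "three", "four", "five", "six", "seven", "eight",
      "nine", "ten", "eleven")),
    synonyms = "", definition_count = 0L, property_count = 0L,
    parents = c("", paste0("O2:B", 1:10))
  )
  o2 <- ontology(dplyr::bind_rows(o2_anc, tibble::tibble(
    id = c("O2:PCN", "O2:TON"),
    pref_label = c("phenoxymethylpenicillin", "tonsillitis"),
    synonyms = c("penicillin", ""),
    definition_count = c(0L, 0L),
    property_count = c(3L, 2L),
    parents = c("O2:B5", "O2:B11")
  )), acronym = "O2", declared_size = 800)

  list(doc = input_document("Penicillin is an antibiotic used to treat tonsillitis"),
       ontologies = list(O1 = o1, O2 = o2),
       metadata = fixture_metadata(c("O1", "O2")),
       config = recommender_config())
}

# small two-repository metadata table (equal weights) for the toy bundles
fixture_metadata <- function(acronyms) {
  repositories <- tibble::tibble(
    repository = c("UMLS", "BIOPORTAL"),
    presence_weight = c(0.5, 0.5),
    visits_weight = c(0.5, 0.5)
  )
  presence <- c(1L, 1L, 0L, 1L)
  visits <- c(120L, 2000L, 10L, 400L)
  n <- length(acronyms)
  usage <- tibble::tibble(
    ontology = rep(acronyms, each = 2),
    repository = rep(repositories$repository, n),
    presence = presence[seq_len(2 * n)],
    visits = visits[seq_len(2 * n)]
  )
  repository_metadata(repositories, usage)
}
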