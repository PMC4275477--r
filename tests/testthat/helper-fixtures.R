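# Hand-written toy terminology: a small French/English medical vocabulary
# exercising hierarchy, synonyms, acronyms (one ambiguous), a metaterm, a
# predefined query, and an untranslated supplementary concept. Written
# directly as TSV so tests of the loader do not depend on the generator.
toy_terminology_dir <- function(dir = tempfile("toyterm")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(file, lines) writeLines(lines, file.path(dir, file), useBytes = TRUE)
  w("descriptors.tsv", c(
    "ui\ttree_numbers\tsee_also",
    "D001\tC04.1\t",
    "D002\tC10.2\tD008",
    "D003\tF01.1\t",
    "D004\tC06.4\t",
    "D005\tF04\t",
    "D006\tN02.3\t",
    "D007\tD01.5\t",
    "D008\tC01\t",
    "D009\tC01.1\t",
    "D010\tC01.2\t"
  ))
  w("qualifiers.tsv", c("ui", "Q001", "Q002"))
  w("supplementary.tsv", c(
    "ui\tmapped_descriptors",
    "S001\tD007"
  ))
  w("metaterms.tsv", c(
    "ui\tlinked",
    "MT01\tD005;D006",
    "MT02\tD005;D006;D001",
    "MT03\tD001"
  ))
  w("predefined.tsv", c(
    "ui\texpression",
    "PQ01\tD007/Q001"
  ))
  w("labels.tsv", c(
    "ui\tlang\tkind\ttext\tambiguous",
    "D001\tfre\tpreferred\tsarcoïdose\t0",
    "D001\teng\tpreferred\tsarcoidosis\t0",
    "D002\tfre\tpreferred\taccident vasculaire cérébral\t0",
    "D002\tfre\tacronym\tAVC\t0",
    "D002\teng\tpreferred\tstroke\t0",
    "D003\tfre\tpreferred\tallaitement maternel\t0",
    "D003\tfre\tsynonym\tallaitement au sein\t0",
    "D003\teng\tpreferred\tbreast feeding\t0",
    "D004\tfre\tpreferred\tmaladie de Crohn\t0",
    "D004\teng\tpreferred\tCrohn disease\t0",
    "D005\tfre\tpreferred\tpsychiatrie\t0",
    "D005\teng\tpreferred\tpsychiatry\t0",
    "D006\tfre\tpreferred\thôpital psychiatrique\t0",
    "D006\teng\tpreferred\tpsychiatric hospital\t0",
    "D007\tfre\tpreferred\tsodium\t0",
    "D007\teng\tpreferred\tsodium\t0",
    "D008\tfre\tpreferred\tinfection\t0",
    "D008\teng\tpreferred\tinfection\t0",
    "D009\tfre\tpreferred\tgrippe\t0",
    "D009\tfre\tacronym\tZZV\t1",
    "D009\teng\tpreferred\tinfluenza\t0",
    "D010\tfre\tpreferred\tcoqueluche\t0",
    "D010\tfre\tacronym\tZZV\t1",
    "D010\teng\tpreferred\twhooping cough\t0",
    "Q001\tfre\tpreferred\tsang\t0",
    "Q001\teng\tpreferred\tblood\t0",
    "Q002\tfre\tpreferred\tchirurgie\t0",
    "Q002\teng\tpreferred\tsurgery\t0",
    "S001\teng\tpreferred\tzamifenacin\t0",
    "MT01\tfre\tpreferred\tpsychiatrie\t0",
    "MT01\teng\tpreferred\tpsychiatry\t0",
    "MT02\tfre\tpreferred\tneuropsychiatrie\t0",
    "MT02\teng\tpreferred\tneuropsychiatry\t0",
    "MT03\tfre\tpreferred\tgranulomatose\t0",
    "MT03\teng\tpreferred\tgranulomatosis\t0",
    "PQ01\tfre\tpreferred\tnatrémie\t0",
    "PQ01\teng\tpreferred\tnatremia\t0"
  ))
  dir
}

toy_terminology <- local({
  store <- NULL
  function() {
    if (is.null(store)) store <<- read_terminology(toy_terminology_dir())
    store
  }
})

# Hand-written citation XML covering the parser's branches: vernacular
# titles, multiple languages, qualifiers, major flags, automatic indexing,
# a missing year, a DOI.
toy_citations_xml <- function() {
  paste0(
    '<?xml version="1.0"?>\n<PubmedArticleSet>',
    '<PubmedArticle><MedlineCitation><PMID>1</PMID><Article>',
    '<Journal><Title>Revue de pneumologie</Title>',
    '<JournalIssue><PubDate><Year>2013</Year></PubDate></JournalIssue></Journal>',
    '<ArticleTitle>[Pulmonary sarcoidosis].</ArticleTitle>',
    '<Abstract><AbstractText>Etude de la sarcoïdose pulmonaire.</AbstractText></Abstract>',
    '<Language>fre</Language>',
    '<PublicationTypeList><PublicationType>Journal Article</PublicationType></PublicationTypeList>',
    '<VernacularTitle>La sarcoïdose pulmonaire</VernacularTitle>',
    '</Article>',
    '<MedlineJournalInfo><Country>France</Country></MedlineJournalInfo>',
    '<MeshHeadingList><MeshHeading>',
    '<DescriptorName UI="D001" MajorTopicYN="Y">sarcoidosis</DescriptorName>',
    '<QualifierName UI="Q002" MajorTopicYN="N">surgery</QualifierName>',
    '</MeshHeading></MeshHeadingList>',
    '</MedlineCitation>',
    '<PubmedData><ArticleIdList><ArticleId IdType="doi">10.1000/synthetic.1</ArticleId>',
    '</ArticleIdList></PubmedData></PubmedArticle>',

    '<PubmedArticle><MedlineCitation><PMID>2</PMID><Article>',
    '<Journal><Title>Revue de pneumologie</Title>',
    '<JournalIssue><PubDate><Year>2010</Year></PubDate></JournalIssue></Journal>',
    '<ArticleTitle>Sarcoidosis without vernacular title.</ArticleTitle>',
    '<Language>fre</Language>',
    '</Article>',
    '<MedlineJournalInfo><Country>France</Country></MedlineJournalInfo>',
    '<MeshHeadingList><MeshHeading>',
    '<DescriptorName UI="D001" MajorTopicYN="N">sarcoidosis</DescriptorName>',
    '</MeshHeading></MeshHeadingList>',
    '</MedlineCitation></PubmedArticle>',

    '<PubmedArticle><MedlineCitation><PMID>3</PMID><Article>',
    '<Journal><Title>English Journal</Title>',
    '<JournalIssue><PubDate><Year>2012</Year></PubDate></JournalIssue></Journal>',
    '<ArticleTitle>An English-language study.</ArticleTitle>',
    '<Language>eng</Language>',
    '</Article>',
    '<MedlineJournalInfo><Country>England</Country></MedlineJournalInfo>',
    '</MedlineCitation></PubmedArticle>',

    '<PubmedArticle><MedlineCitation><PMID>4</PMID><Article>',
    '<Journal><Title>Revue bilingue</Title>',
    '<JournalIssue><PubDate></PubDate></JournalIssue></Journal>',
    '<ArticleTitle>[Influenza surveillance].</ArticleTitle>',
    '<Language>fre</Language><Language>eng</Language>',
    '<VernacularTitle>Surveillance de la grippe</VernacularTitle>',
    '</Article>',
    '<MedlineJournalInfo><Country>France</Country></MedlineJournalInfo>',
    '<MeshHeadingList><MeshHeading>',
    '<DescriptorName UI="D009" MajorTopicYN="Y">influenza</DescriptorName>',
    '</MeshHeading></MeshHeadingList>',
    '</MedlineCitation></PubmedArticle>',

    '<PubmedArticle><MedlineCitation IndexingMethod="Automated"><PMID>5</PMID><Article>',
    '<Journal><Title>Zeitschrift</Title>',
    '<JournalIssue><PubDate><Year>2014</Year></PubDate></JournalIssue></Journal>',
    '<ArticleTitle>[Sarkoidose].</ArticleTitle>',
    '<Language>ger</Language>',
    '<VernacularTitle>Die Sarkoidose</VernacularTitle>',
    '</Article>',
    '<MedlineJournalInfo><Country>Germany</Country></MedlineJournalInfo>',
    '<MeshHeadingList><MeshHeading>',
    '<DescriptorName UI="D001" MajorTopicYN="Y">sarcoidosis</DescriptorName>',
    '</MeshHeading></MeshHeadingList>',
    '</MedlineCitation></PubmedArticle>',
    '</PubmedArticleSet>'
  )
}

# Small deterministic synthetic world shared by search/eval/cli tests.
toy_world <- local({
  world <- NULL
  function() {
    if (is.null(world)) {
      mesh_dir <- tempfile("mesh")
      generate_mini_mesh(mesh_dir, seed = 42)
      store <- read_terminology(mesh_dir)
      corpus_dir <- tempfile("corpus")
      out <- generate_corpus(
        corpus_spec(seed = 42, n_citations = 120, n_queries = 3,
                    planted_per_query = 10),
        store, corpus_dir
      )
      subset <- filter_language(parse_citations(out$xml), "fre")
      index <- build_index(subset, store, "fre")
      world <<- list(mesh_dir = mesh_dir, store = store,
                     corpus_dir = corpus_dir, corpus = out,
                     subset = subset, index = index)
    }
    world
  }
})
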