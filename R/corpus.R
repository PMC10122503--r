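# Synthetic Finnish-style smoking-status sentence generator.
#
# Sentences are built from per-class template families with slot fillers for
# counts, months and years, then optionally perturbed at character level.
# Every current/ex/never template carries at least one of the word stems
# tupak*/aski*/smok* so the candidate-sentence filter is exercised exactly as
# in the real extraction step; a few "unknown" templates carry no stem.

# Slots: {N} count, {F} pack fraction, {M} month, {YY} 2-digit year, {Y} year,
# {Y2} later year. Family names document the clinically hard cases: a quit
# statement with a date is an ex-smoker, without a date it is unknown.
.corpus_templates <- list(
  current = list(
    daily_smoker      = "potilas tupakoi {N} savuketta päivässä",
    still_smokes      = "tupakoi edelleen noin {N} savuketta päivässä",
    pack_a_day        = "polttaa {F} askia päivässä",
    continues         = "jatkaa edelleen tupakointia vieroituksesta huolimatta",
    daily_tobacco     = "potilas polttaa päivittäin tupakkaa",
    smokes_daily      = "tupakoi päivittäin",
    english_current   = "patient is a current smoker and smokes daily",
    ongoing           = "tupakointi jatkuu edelleen",
    pack_per_day      = "polttaa {F} askia vuorokaudessa"
  ),
  ex = list(
    quit_with_date    = "lopettanut tupakoinnin {M}/{YY}",
    quit_year         = "tupakoinnin lopetus vuonna {Y}",
    smoked_years      = "tupakoi vuosina {Y} {Y2}",
    quit_year_short   = "lopettanut tupakoinnin {Y}",
    former_quit       = "ex tupakoitsija tupakointi loppunut {Y}",
    quit_years_ago    = "entinen tupakoitsija lopetti {N} vuotta sitten",
    english_quit      = "quit smoking in {Y}",
    smokefree_since   = "tupakoinnin lopettanut {Y} alkaen savuton",
    quit_pack_habit   = "lopettanut askin päivässä tupakoinnin vuonna {Y}"
  ),
  never = list(
    never_smoked      = "ei ole koskaan tupakoinut",
    denies_all        = "potilas ei tupakoi eikä ole koskaan tupakoinut",
    no_smoking_ever   = "ei tupakointia koskaan",
    english_never     = "never smoker ei tupakkatuotteita",
    lifelong_nonsmoker = "elinikäinen tupakoimattomuus ei koskaan tupakoinut",
    denies_completely = "kieltää tupakoinnin kokonaan ei koskaan aloittanut",
    not_even_pack     = "ei koskaan tupakoinut ei askiakaan",
    english_has_never = "has never smoked"
  ),
  unknown = list(
    smoked_before     = "on tupakoinut aiemmin",
    quit_no_date      = "lopettanut tupakoinnin hiljattain",
    long_history      = "pitkä tupakointihistoria",
    pack_years        = "tupakoinut {N} askivuotta",
    status_unclear    = "tupakointi epäselvä",
    e_cigarette       = "sähkötupakka käytössä päivittäin",
    english_unclear   = "smoking history unclear",
    no_exact_info     = "tupakoinnista ei tarkkaa tietoa",
    no_stem_nicotine  = "nikotiinikorvaushoito käytössä",
    no_stem_nrt       = "ei tarkempia tietoja nikotiinituotteista"
  )
)

#' Sentence template families used by the corpus generator
#'
#' @return data frame with columns `label`, `family`, `template`. Families
#'   encode the clinically hard cases: `quit_with_date` ("lopettanut
#'   tupakoinnin 3/20") is labelled `ex`, whereas `quit_no_date`
#'   ("lopettanut tupakoinnin hiljattain", i.e. quit recently) is labelled
#'   `unknown`, and pack-year mentions are `unknown`.
#' @export
corpus_templates <- function() {
  do.call(rbind, lapply(names(.corpus_templates), function(lab) {
    tpl <- .corpus_templates[[lab]]
    data.frame(label = lab, family = names(tpl),
               template = unlist(tpl, use.names = FALSE),
               stringsAsFactors = FALSE)
  }))
}

# Render n instances of one template, filling all slots vectorized.
# {Y} and {Y2} share a draw so year ranges come out ordered.
.render_template <- function(template, n) {
  slots <- regmatches(template, gregexpr("\\{[A-Z0-9]+\\}", template))[[1]]
  if (!length(slots)) return(rep.int(template, n))
  parts <- strsplit(template, "\\{[A-Z0-9]+\\}")[[1]]
  y <- sample(1970:2018, n, replace = TRUE)
  fill <- function(slot) switch(
    slot,
    "{N}"  = as.character(sample(2:40, n, replace = TRUE)),
    "{F}"  = sample(c("1", "2", "puoli"), n, replace = TRUE),
    "{M}"  = as.character(sample(1:12, n, replace = TRUE)),
    "{YY}" = sprintf("%02d", sample(0:21, n, replace = TRUE)),
    "{Y}"  = as.character(y),
    "{Y2}" = as.character(y + sample(1:15, n, replace = TRUE)))
  out <- parts[1]
  for (i in seq_along(slots)) {
    out <- paste0(out, fill(slots[i]),
                  if (i + 1 <= length(parts)) parts[i + 1] else "")
  }
  out
}

# Character-level perturbation of tokens; stem-bearing and single-character
# tokens are left intact so class-defining evidence survives the noise.
.perturb_many <- function(txt, noise_rate) {
  if (noise_rate <= 0) return(txt)
  toks_list <- strsplit(txt, " ", fixed = TRUE)
  nt <- lengths(toks_list)
  hits <- stats::runif(sum(nt)) < noise_rate
  grp <- rep.int(seq_along(txt), nt)
  any_hit <- rowsum(as.integer(hits), grp) > 0
  hit_split <- split(hits, grp)
  for (i in which(any_hit[, 1])) {
    toks <- toks_list[[i]]
    hit <- hit_split[[i]]
    protect <- grepl("^(tupak|aski|smok)", toks) | nchar(toks) < 2
    for (k in which(hit & !protect)) {
      tk <- strsplit(toks[k], "")[[1]]
      pos <- sample(seq_along(tk), 1)
      op <- sample(c("swap", "drop", "dup"), 1)
      if (op == "swap" && pos < length(tk)) {
        tk[c(pos, pos + 1)] <- tk[c(pos + 1, pos)]
      } else if (op == "drop" && length(tk) > 1) {
        tk <- tk[-pos]
      } else {
        tk <- append(tk, tk[pos], after = pos)
      }
      toks[k] <- paste(tk, collapse = "")
    }
    txt[i] <- paste(toks, collapse = " ")
  }
  txt
}

.render_sentences <- function(labels, noise_rate) {
  fams <- character(length(labels))
  txt <- character(length(labels))
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    tpl <- .corpus_templates[[lab]]
    pick <- sample(length(tpl), length(idx), replace = TRUE)
    fams[idx] <- names(tpl)[pick]
    for (k in seq_along(tpl)) {
      sel <- idx[pick == k]
      if (length(sel)) txt[sel] <- .render_template(tpl[[k]], length(sel))
    }
  }
  txt <- .perturb_many(txt, noise_rate)
  list(text = txt, family = fams)
}

#' Configuration for the synthetic sentence corpus
#'
#' @param n_sentences number of sentences to generate.
#' @param class_mix named probability vector over the classes
#'   `current`, `ex`, `never`, `unknown`; must sum to 1.
#' @param noise_rate fraction of tokens receiving a character-level
#'   perturbation (swap/drop/duplicate), in `[0, 1]`.
#' @param seed integer seed; the corpus is a pure function of the config.
#' @return object of class `corpus_config`.
#' @export
corpus_config <- function(n_sentences = 10000,
                          class_mix = c(current = 0.25, ex = 0.25,
                                        never = 0.25, unknown = 0.25),
                          noise_rate = 0.05, seed = 1L) {
  if (!is.numeric(n_sentences) || n_sentences < 1)
    stop("n_sentences must be a positive integer", call. = FALSE)
  if (is.null(names(class_mix))) names(class_mix) <- SMOKING_CLASSES
  class_mix <- class_mix[SMOKING_CLASSES]
  if (anyNA(class_mix))
    stop("class_mix must be named over current/ex/never/unknown",
         call. = FALSE)
  check_prob_vector(class_mix, "class_mix")
  if (!is.numeric(noise_rate) || noise_rate < 0 || noise_rate > 1)
    stop("noise_rate must lie in [0, 1]", call. = FALSE)
  structure(list(n_sentences = as.integer(n_sentences),
                 class_mix = class_mix, noise_rate = noise_rate,
                 seed = as.integer(seed)),
            class = "corpus_config")
}

#' Generate a labelled synthetic sentence corpus
#'
#' Draws class labels from `class_mix`, renders one sentence per label from
#' the template families ([corpus_templates()]), fills date/amount slots,
#' and applies character-level noise. Every current/ex/never sentence
#' contains at least one of the stems `tupak`/`aski`/`smok`; some unknown
#' sentences deliberately do not, to exercise the candidate filter.
#' Output is deterministic given the config seed.
#'
#' @param config a [corpus_config()].
#' @return data frame with columns `sentence_id`, `patient_id`,
#'   `timestamp` (Date), `text`, `label`, `family`.
#' @export
generate_corpus <- function(config = corpus_config()) {
  stopifnot(inherits(config, "corpus_config"))
  with_seed(config$seed, {
    n <- config$n_sentences
    labels <- sample(SMOKING_CLASSES, n, replace = TRUE,
                     prob = config$class_mix)
    rend <- .render_sentences(labels, config$noise_rate)
    data.frame(
      sentence_id = seq_len(n),
      patient_id = sprintf("P%06d", sample.int(max(1L, n %/% 2L), n,
                                               replace = TRUE)),
      timestamp = as.Date("2014-01-01") +
        sample.int(as.integer(as.Date("2019-12-31") - as.Date("2014-01-01")),
                   n, replace = TRUE),
      text = rend$text,
      label = labels,
      family = rend$family,
      stringsAsFactors = FALSE
    )
  })
}
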