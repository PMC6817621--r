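#' Specification of a synthetic screening cohort
#'
#' Bundles the parameters of the generative model used for simulation
#' studies: diagnostic labels are Bernoulli with the study prevalence
#' (default 34/99); standardized text scores are class-shifted normals; the
#' latent trait follows the latent regression
#' \eqn{\theta_n = b_0 + b_1 y_n + \varepsilon_n} (defaults
#' \eqn{b_0 = -0.41}, \eqn{b_1 = 1.44}, \eqn{\sigma^2 = 3.57}); item
#' responses are Bernoulli draws from the 2PL item response function; and
#' narratives are class-conditional unigram multinomials over a stem
#' vocabulary seeded with the published PTSD- and non-PTSD-associated
#' keyword stems.
#'
#' @param n cohort size (default 99).
#' @param prevalence probability of a positive (case) label, strictly in
#'   (0, 1); default 34/99.
#' @param b0,b1,sigma2 latent regression defaults (-0.41, 1.44, 3.57).
#' @param y_gap separation of the class-conditional text-score means, in
#'   pre-standardization SD units (default 2).
#' @param text_effect log-linear tilt of the narrative keyword
#'   distributions per unit of text-score signal (default 0.6, calibrated
#'   so that a held-out product-score classifier reaches accuracy near the
#'   mid-0.8 range typical of narrative-based PTSD screening; 0 means
#'   narratives carry no class signal).
#' @param vocab_size total stem vocabulary size including the 20 signal
#'   stems (default 100).
#' @param doc_length mean narrative length in tokens (default 150, the
#'   recommended minimum narrative length).
#' @param seed integer seed making every generator a pure function of this
#'   spec.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 99L, prevalence = 34 / 99, b0 = -0.41,
                        b1 = 1.44, sigma2 = 3.57, y_gap = 2,
                        text_effect = 0.6, vocab_size = 100L,
                        doc_length = 150L, seed = 1L) {
  stopifnot(n >= 2L, prevalence > 0, prevalence < 1, sigma2 > 0,
            vocab_size >= 20L, doc_length >= 1L, text_effect >= 0,
            is.finite(b0), is.finite(b1))
  structure(list(n = as.integer(n), prevalence = prevalence, b0 = b0,
                 b1 = b1, sigma2 = sigma2, y_gap = y_gap,
                 text_effect = text_effect,
                 vocab_size = as.integer(vocab_size),
                 doc_length = as.integer(doc_length),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# published most-frequent unique stems of the two training corpora;
# used to seed the synthetic vocabulary
.PTSD_STEMS <- c("rape", "flashback", "fire", "involv", "avoid", "incid",
                 "date", "tower", "men", "fault")
.NONPTSD_STEMS <- c("test", "hardli", "tumor", "tight", "excit", "evil",
                    "pleasur", "vision", "frantic", "funni")

.synth_vocab <- function(vocab_size) {
  n_fill <- vocab_size - 20L
  # neutral filler stems; endings drawn from consonants that no Porter
  # suffix rule matches, so every filler is a fixed point of preprocessing
  cons <- c("b", "d", "f", "g", "k", "m", "p", "r", "t", "w")
  fillers <- paste0("stem", c(t(outer(cons, cons, paste0))))[seq_len(n_fill)]
  c(.PTSD_STEMS, .NONPTSD_STEMS, fillers)
}

#' Generate labels, text scores and latent traits
#'
#' Labels are Bernoulli(prevalence) (1 = case, 2 = non-case); the raw text
#' score is standard normal shifted upward by `y_gap` for cases and then
#' standardized over the cohort; the trait is
#' \eqn{\theta_n = b_0 + b_1 y_n + \varepsilon_n} with
#' \eqn{\varepsilon_n \sim N(0, \sigma^2)}. Deterministic given the spec.
#'
#' @param spec a [cohort_spec()].
#' @return list with `labels` (integer 1/2), `y` (standardized scores) and
#'   `theta`.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  labels <- ifelse(stats::runif(spec$n) < spec$prevalence, 1L, 2L)
  y_raw <- stats::rnorm(spec$n) + spec$y_gap * (labels == 1L)
  y <- standardize_scores(y_raw)
  theta <- spec$b0 + spec$b1 * y +
    stats::rnorm(spec$n, 0, sqrt(spec$sigma2))
  list(labels = labels, y = y, theta = theta)
}

#' Generate 2PL item responses for given traits
#'
#' Each cell is an independent Bernoulli draw with success probability
#' [irf_2pl()] at the person's trait and the item's parameters.
#'
#' @param thetas numeric vector of latent traits.
#' @param bank an `item_bank`.
#' @param seed integer seed.
#' @return N x I integer matrix with person ids `P1..Pn` as row names and
#'   item ids as column names.
#' @export
gen_item_responses <- function(thetas, bank, seed = 1L) {
  stopifnot(is.numeric(thetas), length(thetas) >= 1L)
  set.seed(as.integer(seed))
  n <- length(thetas)
  P <- stats::plogis(thetas %o% bank$alpha -
                       matrix(bank$alpha * bank$beta, n, nrow(bank),
                              byrow = TRUE))
  X <- matrix(stats::rbinom(length(P), 1L, P), n, nrow(bank),
              dimnames = list(paste0("P", seq_len(n)), bank$item_id))
  X
}

#' Generate synthetic tokenized narratives
#'
#' Draws each document from a class-conditional unigram multinomial over
#' the spec's stem vocabulary. Keyword probabilities follow a log-linear
#' tilt: the weight of a case-associated stem is
#' \eqn{\exp(\texttt{text\_effect} \cdot s_n)} and of a non-case stem
#' \eqn{\exp(-\texttt{text\_effect} \cdot s_n)}, where the per-person
#' signal \eqn{s_n} is the supplied text score `y[n]`, or, when `y` is
#' omitted, the class-mean shift (`+y_gap/2` for cases, `-y_gap/2`
#' otherwise). Passing the cohort's `y` couples the narratives to the same
#' signal that drives the latent trait, so that scoring the narratives
#' recovers a covariate consistent with the generating regression;
#' with `text_effect = 0` the narratives carry no class signal at all.
#' Document lengths are Poisson with mean `spec$doc_length` (at least 10).
#'
#' @param labels integer vector of class labels (1/2).
#' @param spec a [cohort_spec()].
#' @param y optional numeric per-person signal, typically `gen_cohort(spec)$y`.
#' @return list of labeled `tokenized_doc` objects (tokens are stems).
#' @export
gen_narratives <- function(labels, spec, y = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), all(labels %in% c(1L, 2L)))
  if (!is.null(y)) stopifnot(length(y) == length(labels))
  set.seed(spec$seed + 1L)  # offset: independent of the trait stream
  vocab <- .synth_vocab(spec$vocab_size)
  delta <- c(rep(1, 10L), rep(-1, 10L),
             rep(0, spec$vocab_size - 20L)) * spec$text_effect
  s <- if (is.null(y)) {
    ifelse(labels == 1L, spec$y_gap / 2, -spec$y_gap / 2)
  } else y
  lens <- pmax(10L, stats::rpois(length(labels), spec$doc_length))
  lapply(seq_along(labels), function(i) {
    w <- exp(delta * s[i])
    toks <- sample(vocab, lens[i], replace = TRUE, prob = w / sum(w))
    tokenized_doc(toks, id = sprintf("N%04d", i), label = labels[i])
  })
}

#' Simulate a complete synthetic screening study
#'
#' Chains [gen_cohort()], [gen_narratives()] (coupled to the cohort's text
#' scores) and [gen_item_responses()] under one spec.
#'
#' @param spec a [cohort_spec()].
#' @param bank an `item_bank` (default [ncsr_bank()]).
#' @return list with `spec`, `labels`, `y`, `theta`, `docs`, `responses`.
#' @export
simulate_study <- function(spec = cohort_spec(), bank = ncsr_bank()) {
  coh <- gen_cohort(spec)
  docs <- gen_narratives(coh$labels, spec, y = coh$y)
  X <- gen_item_responses(coh$theta, bank, seed = spec$seed + 2L)
  list(spec = spec, labels = coh$labels, y = coh$y, theta = coh$theta,
       docs = docs, responses = X)
}
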