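# Template bank for the synthetic psychiatric-note generator. Each category
# sentence embeds the mention taxonomy the classifiers must handle: affirmed
# and negated ideation, affirmed and negated attempts, neutral questionnaire
# titles and subheadings, historical mentions, non-patient experiencers, and
# self-harm-without-intent statements. Affirmed sentences never contain a
# packaged negation cue; every affirmed attempt sentence contains at least
# one packaged attempt-dictionary term, so detector recall on synthetic truth
# is structural.

.synth_categories <- c("affirmed_ideation", "negated_ideation",
                       "affirmed_attempt", "negated_attempt", "neutral_title",
                       "historical", "experiencer_other",
                       "self_harm_no_intent", "filler")

.synth_fill <- list(
  name = c("Alex", "Sam", "Jordan", "Casey", "Morgan", "Jamie", "Taylor",
           "Robin", "Charlie", "Ashley"),
  drug = c("paracetamol", "diazepam", "sertraline", "ibuprofen", "zopiclone",
           "citalopram", "aspirin", "mirtazapine"),
  place = c("home", "the ward", "the clinic", "the day hospital",
            "the emergency department"),
  n = as.character(2:40),
  year = as.character(1995:2016))

.synth_templates <- list(
  affirmed_ideation = c(
    "ongoing suicidal ideation noted at review",
    "{name} reports active suicidal ideation with a plan",
    "presents with persistent suicidal ideation and low mood",
    "suicidal ideation remains prominent on the ward",
    "{name} describes frequent suicidal ideation this week",
    "mental state examination revealed marked suicidal ideation",
    "she discussed her suicidal ideation with the team at {place}",
    "worsening suicidal ideation since stopping {drug}"),
  negated_ideation = c(
    "denied any suicidal ideation or intent",
    "no suicidal ideation or plans elicited today",
    "{name} does not report suicidal ideation at present",
    "denies current suicidal ideation",
    "nil suicidal ideation on direct questioning",
    "never expressed suicidal ideation during admission",
    "she would not endorse suicidal ideation when asked"),
  affirmed_attempt = c(
    "{name} took an overdose of {n} {drug} tablets in a suicide attempt",
    "made a serious suicide attempt by hanging and was admitted to {place}",
    "{name} attempted suicide by jumping from a height and sustained injuries",
    "presented to {place} following a suicide attempt by overdose of {drug}",
    "this was a genuine suicide attempt and she required medical treatment",
    "{name} was found after an attempt to end her life with {drug}",
    "admitted after she attempted suicide by taking {n} tablets of {drug}",
    "the overdose was a deliberate suicide attempt with clear intent to die",
    # terse telegraphic affirmations typical of event notes: these share
    # their surface with questionnaire titles, the ambiguity the
    # post-processing rules exist for
    "suicide attempt by overdose of {drug} last night",
    "admitted to {place} following suicide attempt",
    "suicide attempt this week by hanging"),
  negated_attempt = c(
    "{name} said she would not attempt to take her life",
    "denies any suicide attempt in recent weeks",
    "there was no suicide attempt during this admission",
    "did not attempt suicide and has no plans to do so",
    "she denied that this was a suicide attempt",
    "{name} has never attempted suicide"),
  neutral_title = c(
    "Suicide attempts/ideation",
    "b) Suicide attempts x",
    "History of previous suicide attempts",
    "Past suicide attempts",
    "Have you ever attempted suicide?",
    "Suicide attempts",
    "4) Suicide attempts"),
  historical = c(
    "history of attempted suicide in {year}",
    "past history of a suicide attempt many years ago",
    "there is a distant history of suicide attempt noted in old records",
    "{name} reportedly attempted suicide many years ago in {year}"),
  experiencer_other = c(
    "her mother attempted suicide when {name} was a child",
    "his father made a suicide attempt in {year}",
    "family history of suicide attempts on the maternal side",
    "her brother attempted suicide and this affects her greatly"),
  self_harm_no_intent = c(
    "{name} reports that the overdose was not a suicide attempt but a way to stop the stress",
    "has claimed cutting himself to achieve relief from stress and denied that this was an attempt to kill himself",
    "{name} states that she wants to die but says that her overdose was not a suicide attempt",
    "has taken {n} tablets of {drug} in the past when feeling sad but not in an attempt to end her life",
    "he reported that the self harm was done with a desire to harm himself and was not a suicide attempt"),
  filler = c(
    "seen at {place} for routine review",
    "{name} attended the outpatient clinic with her care coordinator",
    "medication reviewed and {drug} continued at current dose",
    "sleep remains poor and appetite is reduced",
    "mood reported as stable over the weekend",
    "plan agreed to continue current care package",
    "{name} engaged well during the session",
    "discussed coping strategies and safety planning",
    "referred to psychology for further assessment",
    "awaiting follow up appointment with consultant",
    "family meeting arranged for next week",
    "community team to visit twice weekly"))

fill_template <- function(template) {
  out <- template
  repeat {
    m <- regmatches(out, regexpr("\\{[a-z]+\\}", out))
    if (!length(m)) break
    slot <- substr(m, 2L, nchar(m) - 1L)
    pool <- .synth_fill[[slot]]
    if (is.null(pool)) stopf("unknown template slot '%s'", slot)
    out <- sub(m, sample(pool, 1L), out, fixed = TRUE)
  }
  out
}
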