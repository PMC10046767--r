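# pausekit

Silent pauses are one of the earliest measurable changes in the speech of
people with Alzheimer's disease: lexical retrieval gets harder, so speakers
pause more often and for longer. pausekit is an R package for turning that
observation into an acoustic-only screening pipeline — no transcription, no
language model — aimed at researchers working on speech-based digital
biomarkers.

The pipeline:

1. **Preprocess** — any WAV becomes mono 44,100 Hz (`read_wav()`,
   `preprocess()`).
2. **Voice activity detection** — each 0.03 s frame is scored in six
   sub-bands (80–250, 250–500, 500–1000, 1000–2000, 2000–3000,
   3000–4000 Hz). Band *i*'s log-energy `E_i` is evaluated under a
   two-component Gaussian mixture for the silent state `H0` and one for the
   voiced state `H1`; the per-band evidence is
   `L_i = log2( P(E_i|H1) / P(E_i|H0) )` and the pooled evidence is
   `L_t = sum_i K_i * L_i`. A frame is voiced iff its total energy passes
   the gate `E_t > Tm` and either some `L_i > T_tau` or `L_t > T_a`
   (`fit_vad_model()`, `run_vad()`).
3. **Pause encoding** — the 0/1 frame labels are the feature. They are cut
   into 4 s windows of 133 frames (`pause_sequence()`, `segment_pauses()`),
   summarized (`pause_stats()`) and visualized (`plot_pause_comparison()`).
4. **Classification** — five classic classifiers (LDA, decision tree, KNN,
   linear SVM, tree bagger) predict per segment; a subject's label is the
   majority vote over their segments, and an ensemble pools segment votes
   across feature streams (`train_classifier()`, `predict_subject()`,
   `ensemble_predict()`, `run_experiment()`). Functional acoustic profiles
   sized to the ComParE 2013 (6373) and eGeMAPS (88) standards are
   available as comparison streams (`extract_features()`).
5. **Evaluation** — confusion counts with AD positive, accuracy / precision
   / recall / F1, and a two-way feature × classifier ANOVA with Tukey HSD
   follow-up (`confusion_counts()`, `classification_metrics()`,
   `two_way_anova()`).

A synthetic corpus generator (`speech_gen_config()`, `generate_corpus()`)
produces two-group WAV corpora whose groups differ only in pause structure,
with exact ground-truth frame labels, so the whole pipeline is testable
without clinical recordings.

## Worked example

```r
library(pausekit)

cfg    <- speech_gen_config(n_subjects_per_group = 5, duration = 60, seed = 42)
corpus <- generate_corpus(cfg)           # 5 control + 5 AD-like recordings
model  <- fit_vad_model(corpus$signals)  # calibrate the detector on the corpus

ps <- run_vad(corpus$signals[["ad01"]], model, subject_id = "ad01")
pause_stats(ps)
#> <pause_stats> 20 pauses, mean 1.764 s, pause time 58.8%
pause_stats(run_vad(corpus$signals[["cn01"]], model, subject_id = "cn01"))
#> <pause_stats> 22 pauses, mean 0.574 s, pause time 21.1%

exp <- run_experiment(corpus, streams = "vad_pause",
                      classifiers = c("dt", "tb"), n_runs = 5, seed = 7)
exp
#> <pause_experiment> 5 run(s), vad_pause x dt/tb
#>     stream classifier accuracy
#>  vad_pause         dt      0.9
#>  vad_pause         tb      0.9
```

The AD-like subject pauses for 1.76 s on average and spends 59% of the
recording silent, against 0.57 s and 21% for the control — the configured
3:1 pause-duration contrast coming back out of the detector. Feeding the
binary pause windows to segment-level classifiers and majority-voting per
subject separates the groups at 90% mean accuracy over five reshuffled
subject-disjoint splits (the held-out sets here are tiny — 2 subjects per
run — so per-run accuracies are coarse).

A thin CLI wrapping the same functions ships in `inst/scripts/pausekit`
(`synth`, `extract`, `segment`, `featurize`, `run`).

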