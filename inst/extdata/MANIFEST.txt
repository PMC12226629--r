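Packaged data files (all plain text, UTF-8):

thyroid_bta.yaml
    Fourteen-class search strategy for neck/thyroid ultrasound reports
    (examinations, nodules, echotexture, goitre, surgery, BTA U1-U5
    gradings, derived solitary/normal classes, consistency post-rules).

negex_triggers.txt
    Negation trigger lexicon: phrase<TAB>TAG lines with tags PRE, POST,
    PSEUDO, TERM, UNC. Editable; read by read_negation_lexicon().

synthetic_example_corpus.csv
synthetic_example_labels.csv
    Twelve SYNTHETIC ultrasound reports from generate_corpus(12, seed = 2025)
    with their ground-truth labels (one logical column per class plus an
    'ambiguous' flag). A quick-start corpus for the worked examples; not
    real patient data. Regenerate with:
        radex::generate_corpus(12, seed = 2025)
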