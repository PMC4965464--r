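# Shared column and enum definitions (loaded first).

.STUDY_COLS <- c("study_id", "article_id", "outcome", "timepoint_label",
                 "am_mean", "nm_mean", "n_am", "n_nm", "dispersion_reported",
                 "colonization_pct", "shoot_dw_es", "leaf_p_es", "nm_leaf_np",
                 "leaf_np_es", "stress", "year")

.OUTCOMES <- c("CER", "GS", "E")

.MODERATORS <- c("colonization_pct", "shoot_dw_es", "leaf_p_es",
                 "nm_leaf_np", "leaf_np_es")

.ALL_MODERATORS <- c(.MODERATORS, "year")
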