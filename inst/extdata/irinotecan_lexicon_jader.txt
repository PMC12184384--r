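# JADER-dialect spellings of the same lexicon.
イリノテカン
塩酸イリノテカン
イリノテカン塩酸塩水和物
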