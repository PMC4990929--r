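# NAF-domain seed alignment (synthetic): 21-mer NAF windows extracted
# from 20 synthetic CIPK archetypes at substitution rate 0.1.
# Regenerate with cblscreen::generate_naf_seed_alignment(20, 0.1, 7).
ELSRLSVNAFDLISLSEGRNK
GLSRLSVNAFDLISLSEGEGK
ELSRLSFNAFDLISLSEGRNK
ELKRNSVNAFDLHSLSEGRNK
ELSRLSVNAFDLICLKEGRNK
ELCRLSSNAFDLISLSEGRNK
ELSRLSVNAFDLISLSEGRNK
ELSRYSVNAFDQISLSEGRNK
RLSRLSVNAFDLISLSIGRND
ELSRLSVNAFDLISLSEGRNK
ELSRDSVNAFDLISLSEGRMM
ELSRLSVNAFTLGSLSEGRNK
ELSSLSVNAFDNISLSEGRNK
ELSRLSVNAFDRISLSEGRNV
ELSRLEVNAFQLISLSEGRNK
RLSRLSVNAFDLISLSEGRNK
ELERLSVNAFDQISLSEGRNK
ELSVLSVNAFDLISLSLGRNK
ELSRLSVNAFDLNSLSEGRNK
ELSRLSVNAFDLISGSEGRNK
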