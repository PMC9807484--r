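raw	canonical
miR-126	miR-126-3p
miR-21	miR-21-5p
miR-29a	miR-29a-3p
miR-29c	miR-29c-3p
miR-30c	miR-30c-5p
miR-103a	miR-103a-3p
mIR-103a-3p	miR-103a-3p
miR-311-3p	miR-311-3p
miR-320	miR-320a
miR-122	miR-122-5p
miR-199a	miR-199a-3p
miR-15a	miR-15a-5p
miR-155	miR-155-5p
miR-221	miR-221-3p
miR-26a	miR-26a-5p
miR-503	miR-503-5p
miR-100	miR-100-5p
miR-101	miR-101-3p
miR-30b	miR-30b-5p
miR-130a	miR-130a-3p
miR-143	miR-143-3p
miR-145	miR-145-5p
miR-19a	miR-19a-3p
miR-150	miR-150-5p
miR-125b	miR-125b-5p
miR-130b	miR-130b-3p
miR-144	miR-144-3p
miR-93	miR-93-5p
let-7	let-7a-5p
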