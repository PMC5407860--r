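states,expected
active,active
poised,poised
polycomb,polycomb
mixed,mixed
intermediate,intermediate
background,background
active;poised,mixed
active;polycomb,mixed
active;mixed,mixed
active;intermediate,active
active;background,active
poised;polycomb,poised
mixed;poised,mixed
intermediate;poised,poised
background;poised,poised
mixed;polycomb,mixed
intermediate;polycomb,polycomb
background;polycomb,polycomb
intermediate;mixed,mixed
background;mixed,mixed
background;intermediate,intermediate
active;poised;polycomb,mixed
active;mixed;poised,mixed
active;intermediate;poised,mixed
active;background;poised,mixed
active;mixed;polycomb,mixed
active;intermediate;polycomb,mixed
active;background;polycomb,mixed
active;intermediate;mixed,mixed
active;background;mixed,mixed
active;background;intermediate,active
mixed;poised;polycomb,mixed
intermediate;poised;polycomb,poised
background;poised;polycomb,poised
intermediate;mixed;poised,mixed
background;mixed;poised,mixed
background;intermediate;poised,poised
intermediate;mixed;polycomb,mixed
background;mixed;polycomb,mixed
background;intermediate;polycomb,polycomb
background;intermediate;mixed,mixed
active;mixed;poised;polycomb,mixed
active;intermediate;poised;polycomb,mixed
active;background;poised;polycomb,mixed
active;intermediate;mixed;poised,mixed
active;background;mixed;poised,mixed
active;background;intermediate;poised,mixed
active;intermediate;mixed;polycomb,mixed
active;background;mixed;polycomb,mixed
active;background;intermediate;polycomb,mixed
active;background;intermediate;mixed,mixed
intermediate;mixed;poised;polycomb,mixed
background;mixed;poised;polycomb,mixed
background;intermediate;poised;polycomb,poised
background;intermediate;mixed;poised,mixed
background;intermediate;mixed;polycomb,mixed
active;intermediate;mixed;poised;polycomb,mixed
active;background;mixed;poised;polycomb,mixed
active;background;intermediate;poised;polycomb,mixed
active;background;intermediate;mixed;poised,mixed
active;background;intermediate;mixed;polycomb,mixed
background;intermediate;mixed;poised;polycomb,mixed
active;background;intermediate;mixed;poised;polycomb,mixed
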