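*C0001
 PAY 6 2015
*C0100
 1 600 -999.0 562.6 76.1
 1 603 316.0 444.7 101.4
 1 606 316.5 351.8 117.6
 1 609 324.4 374.3 148.3
 1 612 334.4 215.0 126.0
 1 615 342.7 589.4 106.6
 1 618 346.8 372.7 135.0
 1 621 363.9 583.0 68.9
 1 624 368.1 555.1 77.1
 1 627 389.3 456.0 132.8
 1 630 393.8 588.4 119.3
 1 633 409.2 447.5 74.1
 1 636 432.5 333.4 54.3
 1 639 426.4 338.7 64.0
 1 642 429.2 359.4 71.6
 1 645 433.1 513.9 97.9
 1 648 443.2 215.6 69.7
 1 651 445.9 499.5 121.9
 1 654 429.7 470.9 50.8
 1 657 415.1 268.5 87.5
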