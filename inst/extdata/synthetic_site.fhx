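FHX2 FORMAT
1724 11 10
ddddddddddd
eeeeeeeeeee
mmmmmmmmmmm
ooooooooooo
11111111111
___________
ttttttttttt
00000000000
00000011111
34568902456

-.---------
-.---------
-.---------
-.---------
..---------
..---------
..---------
..---------
..---------
..---------
..---------
..---------
..---------
..---------
..-.-------
..-.-------
..-.-------
..-.-------
..-.-------
..-.-------
..-.-------
..-.-------
..-.-------
..-.-------
..-.-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
....-------
UUDU-------
||||-------
||||-------
||||-------
||||-------
||||-------
||||-------
||||-------
||||-------
||||-------
||||-------
||||-------
||||-------
||||-------
||||-------
||||-------
||||-------
||||-------
||||-------
||||-------
||||-------
||||-------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||UU.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||D|.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.------
||||.-.----
||||.-.----
||||.-.----
||||.-.----
||||.-.----
||||.-.----
||||.-.----
||||.-.----
||||.-.-.--
||||.-.-.--
||||.-.-.--
||||.-.-.--
||||...-.--
||||...-.--
||||...-.--
||||...-.--
||||...-.--
||||...-.--
||||...-.--
||||...-.--
||||...-.--
||||...-.--
||||...-.--
||||...-.--
||||.....--
||||.....--
||||.....--
||||.....--
||||.....--
||||.....--
||||.....--
D|||UD.UU--
||||||.||--
||||||.||--
||||||.||--
||||||.||--
||||||.||--
||||||.||--
||||||.||--
||||||.||--
||||||.||--
||||||.||--
||||||.||--
||||||.||-.
||||||.||-.
||||||.||-.
||||||.||-.
||||||.||-.
||||||.||..
||||||.||..
||||||.||..
||||||.||..
||||||.||..
||||||.||..
||||||.||..
||||||.||..
||||||.||..
||||||.||..
||||||.||..
||||||.||..
U|||U|U||UU
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
|||||||||||
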